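contrast,group,x,n
determinate_rate,under_3,72,185
determinate_rate,3_and_over,63,240
specificity,under_3,20,30
specificity,3_and_over,36,41
sensitivity,female,12,13
sensitivity,male,51,51
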