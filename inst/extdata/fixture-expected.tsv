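key	value
n_up_1.5	31
n_down_1.5	59
sign_H3K4me3_up	1
sig_H3K4me3_up	1
sign_H3K4me3_down	-1
sig_H3K4me3_down	1
sign_H3K27me3_up	-1
sig_H3K27me3_up	1
sign_H3K27me3_down	1
sig_H3K27me3_down	1
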