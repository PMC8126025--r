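# Default compartment mobility templates on the pooled-sample axis (1-48).
# Peak centers follow the fraction windows of the corresponding marker
# profiles; widths and mixture weights are model parameters (see the
# package vignette). One Gaussian component per row; weights sum to 1
# within each compartment.
compartment	peak_center	peak_width	peak_weight
TP	16	1.8	0.8
TP	24	0.8	0.2
ER	19	0.8	0.6
ER	24	0.9	0.4
GA	23.4	0.5	1
TGN	24	0.35	1
Chl-envelope	24.2	1.0	1
TLK	20	0.5	0.5
TLK	23.3	0.7	0.5
MT	20	0.5	0.3
MT	24	0.8	0.7
PM	25.5	1.7	1
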