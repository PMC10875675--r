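# edff Mulliken charges (electrons) for a rigid water monomer, atoms O,H,H.
# Representative B3LYP-scale population-analysis values, synthetic stand-ins.
atom	charge
1	-0.66
2	0.33
3	0.33
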