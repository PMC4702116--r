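chrom	start	end	mean_depth	depth_var	n_bins
chr11	36000000	41578000	154.7	986.0	5578
chr11	41578000	48294000	519.8	6416.0	6716
chr11	48294000	52263000	398.2	3981.6	3969
chr11	52263000	54799000	465.2	4596.8	2536
chr11	54799000	63567000	305.5	4830.3	8768
chr11	63567000	68933000	186.3	2034.0	5366
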