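chr11	41578000	41578001	L
chr11	48294000	48294001	R
chr11	52263000	52263001	L
chr11	54799000	54799001	R
chr11	63567000	63567001	R
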