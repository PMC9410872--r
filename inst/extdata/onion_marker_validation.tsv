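class	description	n_hotspots	n_f1_heterozygous
1	polymorphism_detected	254	230
2	no_variant	91	NA
3	no_call	3	NA
4	one_parent_only	39	NA
5	unfixed	93	NA
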