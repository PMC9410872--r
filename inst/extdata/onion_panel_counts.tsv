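quantity	numerator	denominator
polymorphic_sites_parent1	4642	NA
polymorphic_sites_parent2	3509	NA
no_information_polymorphisms	4463	NA
no_information_unigenes	1004	NA
first_panel_markers	480	NA
first_panel_sites_selected	329	480
second_panel_markers	441	NA
second_panel_sites_selected_b	349	441
second_panel_sites_selected_c	342	441
f1b_heterozygous_markers	331	441
f1c_heterozygous_markers	336	441
f1a_heterozygous_hotspots	283	480
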