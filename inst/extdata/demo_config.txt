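# Demonstration pipeline configuration: a small synthetic tissue with one
# cell type shifted in abundance between the sexes (1.5x vs 0.5x of the
# equal share) and a subset of genes carrying a within-type regulatory sex
# effect. All analysis thresholds are the package defaults.
sim_n_genes = 400
sim_n_cell_types = 4
sim_n_replicates_per_sex = 3
sim_cells_per_sample = 400
sim_regulatory_fraction = 0.1
sim_regulatory_lfc = 3
sim_prop_shift_type = 1
lfc_threshold = 1
fdr_threshold = 0.05
abundance_alpha = 0.01
ds_max = 2
bootstrap_B = 1000
perm_B = 1000
seed = 1
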