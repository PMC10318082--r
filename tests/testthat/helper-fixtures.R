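# shared fixtures built in code at load time (cheap, deterministic)

fix_codes <- generate_well_codes(96, length = 10, d_min = 3, seed = 101)
fix_index <- default_index_table()
fix_struct <- library_structure()

noiseless_params <- function(depth = 50) {
  channel_params(f_on = 1, f_off = 0, depth_mean = depth,
                 depth_dispersion = Inf, sub_error_rate = 0)
}

# hand-build a single well's read with a chosen state, for surgical tests
make_read <- function(well = "A1", excised = TRUE, color = "blue",
                      index = fix_index[1, ], codes = fix_codes,
                      structure = fix_struct) {
  code <- codes$sequence[codes$well == well]
  locus <- if (excised) paste0(structure$loxp, structure$right_flank)
           else paste0(structure$loxp, structure$intervening,
                       structure$loxp, structure$right_flank)
  paste0(index$i7, structure$pad, code,
         if (color == "red") structure$spacer else "",
         structure$left_flank, locus, index$i5)
}

random_grid <- function(seed) {
  set.seed(seed)
  bitgrid(sample(0:1, 96, replace = TRUE))
}
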