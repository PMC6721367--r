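# Small phantoms shared across tests. All geometry is generated in code;
# the coarse grids keep unit tests fast while the acceptance tests use the
# default resolution.

coarse_head <- function(grid_kind = "axisymmetric_2d", spacing = 1e-3,
                        lateral_extent = 0.04, depth = 0.04) {
  build_phantom(default_layers(), grid_kind, spacing, lateral_extent,
                depth)
}

# homogeneous gray-matter block (brain optical properties everywhere)
gm_block <- function(grid_kind, spacing, lateral_extent, depth) {
  build_phantom(list(layer_spec("gray_matter", NA_real_)), grid_kind,
                spacing, lateral_extent, depth)
}

# thermal overrides that silence metabolic heat in every layer
no_metabolism <- function() {
  lapply(setNames(nm = c("scalp_skull", "csf", "gray_matter",
                         "white_matter")),
         function(ts) list(metabolic_heat = 0))
}
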