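# Shared helpers for the test suite.

# A small, fully deterministic single-hole phantom spec.
simple_spec <- function(hd1 = 2.0, hd2 = 1.5, depth = 1.6, center = 4,
                        profile = "auto", slope = 0, line_depth = 1.2,
                        osteophyte = NULL, noise = 0, porosity = 0,
                        seed = 42L) {
  phantom_spec(
    lesion_spec(center, hd1, hd2, depth, profile = profile),
    cement_line_depth_mm = line_depth, cement_line_slope = slope,
    osteophyte = osteophyte, noise_sigma = noise,
    trabecular_porosity = porosity, seed = seed
  )
}

# A two-hole spec with adjacent openings and a sub-line bridge.
bridge_spec <- function(hd1a = 1.6, hd1b = 1.4, da = 1.8, db = 2.0,
                        vd2 = 0.6, mid = 4, slope = 0, seed = 7L) {
  phantom_spec(
    list(lesion_spec(mid - hd1a / 2, hd1a, hd1a * 0.7, da),
         lesion_spec(mid + hd1b / 2, hd1b, hd1b * 0.7, db)),
    cement_line_depth_mm = 1.2, cement_line_slope = slope,
    bridge_vd2_mm = vd2, seed = seed
  )
}
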