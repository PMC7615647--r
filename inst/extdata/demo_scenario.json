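{
  "seed": 1,
  "imaging": { "pixel_size_nm": 100, "line_time_s": 0.25 },
  "scenario": {
    "n_lines": 240,
    "tether": { "total_bp": 20000, "gap_start_nt": null,
                "gap_end_nt": null, "bead_margin_px": 4 },
    "emitters": [
      { "kind": "static", "start_position_um": 2 },
      { "kind": "diffusive", "D_um2_s": 0.04, "start_position_um": 5 }
    ],
    "psf_sigma_px": 1.3,
    "background_counts": 10
  }
}
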