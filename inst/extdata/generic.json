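{
  "name": "generic",
  "description": "Generic warm-adapted ectotherm used for the qualitative model analyses; maturation is the bare exponential form. Synthetic parameter set, not a fitted species.",
  "birth": { "b_topt": 2.2, "t_opt_b": 302, "s": 3.4 },
  "maturation": { "m_tr": 0.015, "t_r": 297, "a_m": 11500,
                  "a_l": null, "t_l_half": null,
                  "a_h": null, "t_h_half": null },
  "juvenile_mortality": { "d_jtr": 0.03, "a_dj": 6260, "t_r": 297 },
  "adult_mortality": { "d_atr": 0.048, "a_da": 14600, "t_r": 297 }
}
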