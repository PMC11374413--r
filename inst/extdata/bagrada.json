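{
  "name": "bagrada",
  "description": "Bagrada hilaris (bagrada bug), invasive, subtropical origin. Fitted thermal reaction norms; temperatures in Kelvin, rates per day. Maturation uses the reduced (high-temperature-decline only) form; A_H and T_H/2 were assigned biologically reasonable values rather than estimated.",
  "birth": { "b_topt": 3.586, "t_opt_b": 306.6, "s": 3.659 },
  "maturation": { "m_tr": 0.0168, "t_r": 297, "a_m": 10671.0,
                  "a_l": null, "t_l_half": null,
                  "a_h": 90000, "t_h_half": 312 },
  "juvenile_mortality": { "d_jtr": 0.0287, "a_dj": 6779.1, "t_r": 297 },
  "adult_mortality": { "d_atr": 0.0926, "a_da": 12355.6, "t_r": 297 }
}
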