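{
  "name": "harlequin",
  "description": "Murgantia histrionica (harlequin bug), naturalized, Mediterranean-adapted. Fitted thermal reaction norms; temperatures in Kelvin, rates per day. Maturation uses the full Sharpe-Schoolfield form; A_L and T_L/2 were assigned (T_L/2 at freezing).",
  "birth": { "b_topt": 0.8921, "t_opt_b": 298.3, "s": 3.085 },
  "maturation": { "m_tr": 0.0138, "t_r": 297, "a_m": 13480,
                  "a_l": -100000, "t_l_half": 273,
                  "a_h": 48150, "t_h_half": 303.8 },
  "juvenile_mortality": { "d_jtr": 0.0343, "a_dj": 5743, "t_r": 297 },
  "adult_mortality": { "d_atr": 0.0029, "a_da": 16824, "t_r": 297 }
}
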