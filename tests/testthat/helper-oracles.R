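# Shared fixtures and independently computed oracle values.
#
# The frozen constants below were obtained by direct high-precision
# evaluation of the closed-form response functions (and, for the niche
# metrics, by independent bounded optimization / bracketed root finding on
# the closed-form growth rate) outside this package; they pin the
# implementation to the formulas rather than to itself.

bag <- tn_species("bagrada")
har <- tn_species("harlequin")
gen <- tn_species("generic")

oracle <- list(
  har_da_299.85 = 0.004968516757557954,   # Arrhenius, 0.0029 * exp(16824*(1/297 - 1/299.85))
  har_dj_292.85 = 0.026078819673995477,
  har_b_292.85  = 0.18737615505543942,
  har_m_299.85  = 0.0190823134491875,
  har_m_296.85  = 0.013158435784724408,
  har_tau_299.85 = 52.404547418362355,
  har_tau_292.85 = 140.19143757731362,
  q_uni_292.85  = 0.02100394070792954,    # Gaussian(0.1, 298.3, 3.085) at 292.85
  q_mono_292.85 = 0.044809884634906295,   # Arrhenius(0.1, 16824, 297) at 292.85
  # niche metrics (Kelvin), from independent optimize/brentq on the closed form
  bag_topt_k = 307.096256, bag_tmin_k = 299.701723, bag_tmax_k = 310.706175,
  har_topt_k = 299.762357, har_tmin_k = 291.258042, har_tmax_k = 303.926815,
  bag_rmax = 0.058596, har_rmax = 0.022679,
  # shared-area overlap fractions (lower-envelope integral / own-niche integral)
  frac_har = 0.254838, frac_bag = 0.098862
)

# default constant-temperature model builders
di_model <- function(traits, t_k)
  model_spec(traits, forcing = temperature_forcing("constant", t_k))

dd_model <- function(traits, acts_on, t_k, strength = 0.1)
  model_spec(traits, default_competition(traits, acts_on, strength),
             temperature_forcing("constant", t_k))
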