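# Murine tissue optical parameters at the two Eu3+ emission wavelengths
# (610 and 630 nm): absorption mu_a (mm^-1), scattering mu_s (mm^-1),
# anisotropy g. Refractive index n defaults to the soft-tissue value 1.37.
adipose:
  "610": {mu_a: 0.0127, mu_s: 21.1547, g: 0.94}
  "630": {mu_a: 0.0069, mu_s: 20.7961, g: 0.94}
heart:
  "610": {mu_a: 0.2015, mu_s: 7.3484, g: 0.85}
  "630": {mu_a: 0.1085, mu_s: 7.0171, g: 0.85}
stomach:
  "610": {mu_a: 0.0384, mu_s: 19.6728, g: 0.92}
  "630": {mu_a: 0.0207, mu_s: 19.0667, g: 0.92}
liver:
  "610": {mu_a: 1.2086, mu_s: 7.4826, g: 0.90}
  "630": {mu_a: 0.6505, mu_s: 7.2334, g: 0.90}
kidneys:
  "610": {mu_a: 0.2258, mu_s: 18.5421, g: 0.86}
  "630": {mu_a: 0.1216, mu_s: 17.6605, g: 0.86}
lungs:
  "610": {mu_a: 0.6687, mu_s: 38.0785, g: 0.94}
  "630": {mu_a: 0.3622, mu_s: 37.4330, g: 0.94}
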