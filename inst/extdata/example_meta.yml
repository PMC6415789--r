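starch_C12_light: {isotope: C12, fraction_role: light, treatment: starch, density: 1.700}
starch_C12_heavy: {isotope: C12, fraction_role: heavy, treatment: starch, density: 1.725}
starch_C13_light: {isotope: C13, fraction_role: light, treatment: starch, density: 1.700}
starch_C13_heavy: {isotope: C13, fraction_role: heavy, treatment: starch, density: 1.725}
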