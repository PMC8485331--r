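name,molar_mass_Da,D_cm2_per_s,source
fluorophore_ref_small,332,1.0e-09,synthetic stand-in; order-of-magnitude value for a small xanthene dye in PDMS
fluorophore_ref_mid,479,2.5e-10,synthetic stand-in; order-of-magnitude value for a rhodamine-class dye in PDMS
fluorophore_ref_large,606,4.0e-11,synthetic stand-in; order-of-magnitude value for a large charged dye in PDMS
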