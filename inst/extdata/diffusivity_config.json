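{
  "mass_exponent": 0.5,
  "note": "Exponent of the inverse mass-ratio scaling used to transfer a measured PDMS diffusivity from a reference molecule to a target molecule. 0.5 is a standard small-molecule-in-elastomer scaling choice; edit alongside the reference diffusivity table if measured values for your compounds exist."
}
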