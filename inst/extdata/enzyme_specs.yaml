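# Default cascade presets for the five coniine-pathway enzymes.
# Fields mirror the arguments of enzyme_seed_spec().
cpks5:
  bait_ids: [CPKS5]
pkr:
  pfam: [PF08659]
aat:
  pfam: [PF00155, PF00202, PF00266]
  mw_range: [45, 65]
  ec_whitelist: ["2.6.1.2", "2.6.1.4", "2.6.1.12", "2.6.1.44"]
  alt_pfam_pass: [PF00202]
cr:
  pfam: [PF00106, PF08659, PF13561]
  cofactor: NADPH-or-both
  ec_prefix: "1.3.1"
csam:
  pfam: [PF03492]
  ec_prefix: "2.1.1.49"
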