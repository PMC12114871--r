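# Small fixtures built in code.

ref_pk <- reference_pk_params()
ref_pd_treated <- reference_pd_params("treated")
ref_pd_control <- reference_pd_params("control")

# Minimal NONMEM-style CSV: one dose row and three concentration rows.
write_tiny_pk_csv <- function(path) {
  writeLines(c(
    "ID,TIME,AMT,DV,EVID,MDV,DVID,ARM",
    "M1,7,10,0,1,1,0,AFT",
    "M1,0.5,0,12.1,0,0,1,AFT",
    "M1,2,0,30.5,0,0,1,AFT",
    "M1,8,0,22.3,0,0,1,AFT"), path)
  path
}

# Tiny three-subject PK dataset used for likelihood-oracle comparisons.
tiny_pk_subjects <- function(seed = 11) {
  cfg <- synthetic_config(seed = seed, n_pk_per_arm = 3, arms = c("AFT"))
  ds <- gen_pk_dataset(cfg)
  recs <- xenopkpd:::obs_records(ds, 1L)
  lapply(split(recs, recs$ID), function(s) {
    s <- s[order(s$TIME), ]
    list(id = s$ID[1], t = s$TIME, dv = s$DV, reg = ds$regimens[[s$ARM[1]]])
  })
}
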