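# Heavy shared fixtures for the end-to-end suite, built once per session.
# Study conditions: vendored genome; reference panel of 30 healthy controls
# at 100,000 fragments (~770x); analysis samples at the generator default
# of 30,000 fragments (~230x).
.study <- new.env(parent = emptyenv())

study_genome <- function() {
  if (is.null(.study$lo)) .study$lo <- mt_reference()
  .study$lo
}

study_cfg <- function() {
  if (is.null(.study$cfg)) {
    lo <- study_genome()
    .study$cfg <- sim_config(ref = lo$reference,
                             annotations = lo$annotations)
  }
  .study$cfg
}

# reference fragmentation profile and its peak set
study_panel <- function() {
  if (is.null(.study$panel)) {
    lo <- study_genome()
    cfgP <- sim_config(ref = lo$reference, annotations = lo$annotations,
                       n_fragments = 100000L)
    gc <- gc_fraction_track(lo$reference)
    profiles <- lapply(1:30, function(i)
      site_profile(simulate_sample(cfgP, "HC", seed = 100L + i),
                   lo$reference, gc_track = gc))
    rz <- reference_profile(profiles)
    .study$panel <- list(profiles = profiles, rz = rz,
                         peaks = call_peaks(rz), gc = gc)
  }
  .study$panel
}

# default 100 MT / 100 HC cohort with its extracted feature matrix
study_cohort <- function() {
  if (is.null(.study$cohort)) {
    lo <- study_genome()
    pan <- study_panel()
    coh <- simulate_cohort(study_cfg(), c(MT = 100L, HC = 100L), seed = 42L)
    fm <- feature_matrix(coh$samples, lo$reference, pan$rz)
    .study$cohort <- list(cohort = coh, features = fm$features,
                          meta = fm$meta)
  }
  .study$cohort
}
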