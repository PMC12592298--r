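# shared helpers: noise-free designs and hand-built profiles

noise_free_design <- function(route, sampling, n_subjects = 6, ...) {
  pk_design(route, sampling = sampling, n_subjects = n_subjects,
            iiv_omega2 = list(), sigma_add = 0, sigma_prop = 0, ...)
}

noise_free_data <- function(route, sampling, n_subjects = 6, ...) {
  generate_pk_dataset(noise_free_design(route, sampling, n_subjects, ...))
}

annotated_from <- function(df, ...) {
  annotate_doses(read_pk_dataset(df), ...)
}

# build a pooled_profile object directly from (tad, conc) vectors
make_profile <- function(tad, conc, route = "bolus", group = "mixed") {
  structure(list(group = group,
                 bins = data.frame(tad = tad, conc = conc,
                                   n_points = rep(1L, length(tad))),
                 n_bins_requested = length(tad), route = route),
            class = "pooled_profile")
}

# single-dose event table helper
single_dose <- function(amount = 100, route = "bolus", rate = 0, time = 0) {
  data.frame(time = time, amount = amount, rate = rate, route = route)
}
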