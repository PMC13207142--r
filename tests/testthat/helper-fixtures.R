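# Small fixtures built in code.

# A compact multi-study simulation used by several tests.
tiny_sim_config <- function(seed = 101L, ...) {
  defaults <- list(
    n_studies = 2L,
    samples_per_group_per_study = c(PS_male = 6L, PS_female = 6L,
                                    Control_male = 6L, Control_female = 6L),
    n_genes = 600L,
    n_shared_degs = 30L,
    n_female_unique_degs = 10L,
    n_male_unique_degs = 10L,
    n_interaction_genes = 6L,
    lib_size_range = c(1.2e7, 3e7),
    seed = seed
  )
  do.call(simulation_config, modifyList(defaults, list(...)))
}

# Deterministic count matrix with controlled column sums.
fixed_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% rownames(m) %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Metadata for a vector of group labels, single study by default.
meta_for_groups <- function(groups, study = "study01", ids = NULL) {
  data.frame(
    sample_id = ids %||% sprintf("s%03d", seq_along(groups)),
    study = rep_len(study, length(groups)),
    condition = ifelse(startsWith(groups, "PS"), "PS", "Control"),
    sex = ifelse(endsWith(groups, "female"), "female", "male"),
    group = groups,
    stringsAsFactors = FALSE
  )
}
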