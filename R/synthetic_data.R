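#' Decay data container
#'
#' The measured or simulated two-dimensional magnetization matrix over the
#' inversion-time ladder (rows) and the CPMG echo train (columns).
#'
#' @param signal Numeric matrix, `n_t1_steps x n_echoes`.
#' @param scheme The [acquisition_scheme()] that produced it.
#' @param provenance Named list of metadata (phenotype, seed, noise_sd, ...).
#' @return An object of class `decay_data` with fields `signal`,
#'   `t1_axis_ms`, `t2_axis_ms`, `scheme`, `provenance`.
#' @export
decay_data <- function(signal, scheme, provenance = list()) {
  stopifnot(is.matrix(signal), inherits(scheme, "acquisition_scheme"))
  if (nrow(signal) != scheme$n_t1_steps || ncol(signal) != scheme$n_echoes)
    stop(sprintf("signal is %d x %d but scheme expects %d x %d",
                 nrow(signal), ncol(signal),
                 scheme$n_t1_steps, scheme$n_echoes))
  structure(list(signal = signal,
                 t1_axis_ms = scheme$t1_ladder_ms,
                 t2_axis_ms = scheme$t2_times_ms,
                 scheme = scheme,
                 provenance = provenance),
            class = "decay_data")
}

#' @export
print.decay_data <- function(x, ...) {
  cat(sprintf("IR-CPMG decay data: %d t1 steps x %d echoes (echo time %g us)\n",
              nrow(x$signal), ncol(x$signal), x$scheme$echo_time_us))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               vapply(x$provenance, format, character(1)),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Simulate an IR-CPMG decay matrix
#'
#' Forward model of the two-dimensional inversion-recovery / CPMG
#' experiment. For inversion time t1 and echo time t2 the noiseless signal
#' from a set of discrete reservoirs is
#' \deqn{s(t_1, t_2) = \sum_k A_k \,(1 - 2\beta e^{-t_1/T_{1,k}})\, e^{-t_2/T_{2,k}}}
#' with inversion efficiency \eqn{\beta = 1} for a perfect 180-degree pulse.
#' A relaxation tail contributes through its log-linearly interpolated
#' sub-reservoirs. Additive i.i.d. Gaussian noise of standard deviation
#' `scheme$noise_sd` is applied when positive (seeded).
#'
#' @param model A [phenotype_model()] (amplitudes normalized).
#' @param scheme An [acquisition_scheme()].
#' @param seed Integer seed for the noise draw, or `NULL` to use the current
#'   RNG state. Ignored when `scheme$noise_sd == 0`.
#' @param efficiency Inversion efficiency beta in (0, 1]; default 1.
#' @return A [decay_data()] object.
#' @export
#' @examples
#' sch <- acquisition_scheme(n_echoes = 200, noise_sd = 0)
#' d <- simulate_decay(preset_phenotype("oxygenated"), sch)
#' dim(d$signal)
simulate_decay <- function(model, scheme, seed = NULL, efficiency = 1) {
  stopifnot(inherits(model, "phenotype_model"),
            inherits(scheme, "acquisition_scheme"))
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must be in (0, 1]")
  comps <- model_components(model)
  t1 <- scheme$t1_ladder_ms
  t2 <- scheme$t2_times_ms
  sig <- matrix(0, length(t1), length(t2))
  for (cm in comps) {
    rec <- 1 - 2 * efficiency * exp(-t1 / cm$t1_ms)
    dec <- exp(-t2 / cm$t2_ms)
    sig <- sig + cm$amplitude * outer(rec, dec)
  }
  if (scheme$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- sig + matrix(stats::rnorm(length(sig), sd = scheme$noise_sd),
                        nrow(sig), ncol(sig))
  }
  decay_data(sig, scheme,
             provenance = list(phenotype = model$state,
                               seed = if (is.null(seed)) NA_integer_ else seed,
                               noise_sd = scheme$noise_sd,
                               efficiency = efficiency))
}

# Deterministic per-subject seed derived from the global seed and subject id,
# stable under cohort extension (adding subjects never reshuffles others).
subject_seed <- function(global_seed, subject_id) {
  h <- sum(utf8ToInt(as.character(subject_id)) *
             (31^(seq_len(nchar(as.character(subject_id))) %% 7)))
  as.integer((as.numeric(global_seed) * 104729 + h * 7919) %% 2147483647)
}

# Multiplicative log-normal jitter of a phenotype model's reservoir
# coordinates and amplitudes (and tail endpoints/amplitude).
jitter_model <- function(model, sdlog) {
  if (sdlog == 0) return(model)
  jit <- function(x) x * stats::rlnorm(1, 0, sdlog)
  res <- lapply(model$reservoirs, function(r)
    relaxation_reservoir(jit(r$t1_ms), jit(r$t2_ms), jit(r$amplitude),
                         r$label))
  tail <- model$tail
  if (!is.null(tail)) {
    s <- c(jit(tail$start["t1_ms"]), jit(tail$start["t2_ms"]))
    e <- c(jit(tail$end["t1_ms"]), jit(tail$end["t2_ms"]))
    if (s[1] <= e[1]) s[1] <- e[1] * 1.05  # preserve downward-running tail
    tail <- tail_spec(s, e, tail$n_components, jit(tail$total_amplitude))
  }
  phenotype_model(model$state, res, tail)
}

#' Default composition of the synthetic 32-subject cohort
#'
#' @return Named integer vector of subjects per phenotype.
#' @export
default_cohort_composition <- function() {
  c(wild_type = 10L, oxidized = 8L, partially_oxidized = 6L,
    hbe = 3L, hbd = 3L, rare_beta_thal = 2L)
}

#' Generate a synthetic cohort of decay data
#'
#' Emulates a multi-subject study: each subject is a preset phenotype whose
#' reservoir T1/T2/amplitudes are jittered multiplicatively (log-normal,
#' default 5%) to capture the strongly subject-specific character of
#' relaxation fingerprints, then forward-simulated at the given acquisition
#' scheme with additive noise. The partially oxidized subtype is the
#' oxidized preset with its tail/T0 amplitude scaled by a per-subject factor
#' drawn uniformly from `partial_range`, emulating intermediate oxidation.
#'
#' Class labels: `oxidized` and `partially_oxidized` map to `disease`,
#' `wild_type` to `non_disease`, hemoglobin variants to `variant`.
#'
#' @param composition Named integer vector of subjects per phenotype; names
#'   from [phenotype_presets()] plus `"partially_oxidized"`. Default
#'   [default_cohort_composition()] (32 subjects).
#' @param scheme An [acquisition_scheme()]; the default uses the standard
#'   acquisition (200 us echo time, 4000 echoes, 32 log t1 steps) at
#'   peak-signal SNR 500.
#' @param jitter_sd Log-normal jitter standard deviation (default 0.05).
#' @param partial_range Range of the tail-amplitude scaling factor for the
#'   partially oxidized subtype (default `c(0.2, 0.8)`).
#' @param seed Integer global seed; expanded deterministically into
#'   per-subject seeds so the cohort is reproducible and extensible.
#' @return A list with `manifest` (data frame: subject_id, phenotype, class,
#'   subtype, seed) and `decays` (named list of [decay_data()]).
#' @export
generate_cohort <- function(composition = default_cohort_composition(),
                            scheme = acquisition_scheme(),
                            jitter_sd = 0.05,
                            partial_range = c(0.2, 0.8),
                            seed = 1L) {
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named vector")
  valid <- c(phenotype_presets(), "partially_oxidized")
  if (!all(names(composition) %in% valid))
    stop("unknown phenotype in composition: ",
         paste(setdiff(names(composition), valid), collapse = ", "))
  composition <- composition[composition > 0]
  n <- sum(composition)
  phenos <- rep(names(composition), composition)
  ids <- sprintf("S%02d", seq_len(n))
  class_of <- function(p) switch(p,
    wild_type = "non_disease",
    oxidized = , partially_oxidized = "disease",
    "variant")
  subtype_of <- function(p) switch(p,
    oxidized = "oxidized_hb",
    partially_oxidized = "partially_oxidized_hb",
    p)
  manifest <- data.frame(
    subject_id = ids,
    phenotype = phenos,
    class = vapply(phenos, class_of, character(1)),
    subtype = vapply(phenos, subtype_of, character(1)),
    seed = vapply(ids, function(id) subject_seed(seed, id), integer(1)),
    stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  decays <- vector("list", n)
  names(decays) <- ids
  for (i in seq_len(n)) {
    set.seed(manifest$seed[i])
    p <- phenos[i]
    if (p == "partially_oxidized") {
      base <- preset_phenotype("oxidized")
      fac <- stats::runif(1, partial_range[1], partial_range[2])
      tl <- base$tail
      tl$total_amplitude <- tl$total_amplitude * fac
      base <- phenotype_model("partially_oxidized", base$reservoirs, tl)
    } else {
      base <- preset_phenotype(p)
    }
    mod <- jitter_model(base, jitter_sd)
    decays[[i]] <- simulate_decay(mod, scheme, seed = manifest$seed[i] + 1L)
    decays[[i]]$provenance$subject_id <- ids[i]
    decays[[i]]$provenance$phenotype <- p
  }
  attr(manifest, "generation") <- list(jitter_sd = jitter_sd,
                                       partial_range = partial_range,
                                       seed = seed,
                                       noise_sd = scheme$noise_sd)
  list(manifest = manifest, decays = decays)
}

#' Binary disease / non-disease labels for a cohort
#'
#' Wild-type subjects are non-disease; oxidized, partially oxidized and
#' hemoglobin-variant subjects are disease (variants present clinical
#' phenotypes such as hemolysis and late methemoglobinemia).
#'
#' @param manifest A cohort manifest data frame.
#' @return Factor with levels `c("non_disease", "disease")`.
#' @export
binary_labels <- function(manifest) {
  factor(ifelse(manifest$class == "non_disease", "non_disease", "disease"),
         levels = c("non_disease", "disease"))
}
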