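# Seeded synthetic generators: paired repertoires built on the packaged
# germline templates, embedding clouds with the compact-reference /
# radial-background geometry the Layer-1 gate assumes, and labelled feature
# matrices with planted informative columns for the Layer-2 test bed.
# All generators are pure functions of their spec (seed included).

#' Synthetic repertoire specification
#'
#' Defaults state the emulated world: CDR-H3 lengths follow a discretised
#' normal with the clinical mean 12.1 and sd 6.65, truncated to [5, 19] (19
#' is the H95-H102 window capacity of the 132-slot grid); framework point
#' mutations at 2% per position (a typical somatic hypermutation load),
#' never touching template cysteines/tryptophans so every generated record
#' stays numberable; 60% kappa light chains.
#'
#' @param n number of paired records.
#' @param mutation_rate per-position framework mutation probability.
#' @param cdrh3_mean,cdrh3_sd,cdrh3_min,cdrh3_max loop-length distribution.
#' @param kappa_fraction probability a record uses the kappa template.
#' @param seed integer seed.
#' @return a `repertoire_spec`.
#' @export
repertoire_spec <- function(n, mutation_rate = 0.02, cdrh3_mean = 12.1,
                            cdrh3_sd = 6.65, cdrh3_min = 5L, cdrh3_max = 19L,
                            kappa_fraction = 0.6, seed = 1L) {
  stopifnot(n >= 0, mutation_rate >= 0, mutation_rate <= 1, cdrh3_mean > 0,
            cdrh3_min >= 1, cdrh3_max <= 19, cdrh3_min <= cdrh3_max)
  structure(list(n = as.integer(n), mutation_rate = mutation_rate,
                 cdrh3_mean = cdrh3_mean, cdrh3_sd = cdrh3_sd,
                 cdrh3_min = as.integer(cdrh3_min),
                 cdrh3_max = as.integer(cdrh3_max),
                 kappa_fraction = kappa_fraction, seed = as.integer(seed)),
            class = "repertoire_spec")
}

#' Generate a synthetic paired repertoire
#'
#' @param spec a [repertoire_spec()].
#' @param status status label attached to every record (default `"library"`).
#' @param prefix id prefix (ids are `<prefix>_00001`, ...); give distinct
#'   prefixes to sets used together in one pipeline run.
#' @return list of [paired_antibody()], deterministic per seed.
#' @export
generate_repertoire <- function(spec, status = "library", prefix = "syn") {
  stopifnot(inherits(spec, "repertoire_spec"))
  refs <- reference_sequences()
  aa_no_cw <- setdiff(AA20, c("C", "W"))
  mutate_fw <- function(seq, rate) {
    ch <- strsplit(seq, "")[[1]]
    can <- which(!(ch %in% c("C", "W")))   # keep anchors intact
    hit <- can[stats::runif(length(can)) < rate]
    if (length(hit)) ch[hit] <- sample(aa_no_cw, length(hit), replace = TRUE)
    paste(ch, collapse = "")
  }
  h_parts <- strsplit(refs[["heavy"]], "DGGYSGDY")[[1]]  # template CDR-H3
  with_seed(spec$seed, {
    lapply(seq_len(spec$n), function(i) {
      len <- round(stats::rnorm(1, spec$cdrh3_mean, spec$cdrh3_sd))
      len <- min(max(len, spec$cdrh3_min), spec$cdrh3_max)
      loop <- paste(sample(aa_no_cw, len, replace = TRUE), collapse = "")
      heavy <- paste0(mutate_fw(h_parts[1], spec$mutation_rate), loop,
                      mutate_fw(h_parts[2], spec$mutation_rate))
      lt <- if (stats::runif(1) < spec$kappa_fraction) "kappa" else "lambda"
      light <- mutate_fw(refs[[lt]], spec$mutation_rate)
      paired_antibody(sprintf("%s_%05d", prefix, i), heavy, light, status = status,
                      light_type = lt)
    })
  })
}

#' Embedding-cloud specification
#'
#' Emulates the Layer-1 geometry: a compact isotropic reference ("clinical")
#' cluster at the origin surrounded by a radially spread background
#' ("library") cloud. Defaults: 144 reference points (the clinical set size),
#' 1000 background points (a desk-scale stand-in for the 10,000-sequence
#' library), background spread 10x the reference scale, and dimension 2 --
#' the generator emulates the radial geometry observed in the two retained
#' principal components, which is where the gate operates; at higher
#' dimensions the radial contrast is diluted by projection.
#'
#' @param n_reference,n_background point counts.
#' @param dimension embedding dimension.
#' @param r_ref reference Gaussian scale; `r_bg` outer background radius
#'   (`r_bg > r_ref > 0`).
#' @param seed integer seed.
#' @return an `embedding_cloud_spec`.
#' @export
embedding_cloud_spec <- function(n_reference = 144L, n_background = 1000L,
                                 dimension = 2L, r_ref = 1, r_bg = 10,
                                 seed = 1L) {
  stopifnot(r_bg > r_ref, r_ref > 0, dimension >= 2)
  structure(list(n_reference = as.integer(n_reference),
                 n_background = as.integer(n_background),
                 dimension = as.integer(dimension),
                 r_ref = r_ref, r_bg = r_bg, seed = as.integer(seed)),
            class = "embedding_cloud_spec")
}

#' Generate labelled embedding clouds
#'
#' Reference points are isotropic Gaussian with per-coordinate sd `r_ref`;
#' background points sit at radii uniform on (r_ref, r_bg) in random
#' directions.
#'
#' @param spec an [embedding_cloud_spec()].
#' @return list: `X` (matrix), `group` (factor `reference`/`background`).
#' @export
generate_embedding_clouds <- function(spec) {
  stopifnot(inherits(spec, "embedding_cloud_spec"))
  with_seed(spec$seed, {
    d <- spec$dimension
    ref <- matrix(stats::rnorm(spec$n_reference * d, sd = spec$r_ref),
                  spec$n_reference, d)
    bg <- matrix(numeric(0), 0, d)
    if (spec$n_background > 0) {
      dir <- matrix(stats::rnorm(spec$n_background * d), spec$n_background, d)
      dir <- dir / sqrt(rowSums(dir^2))
      rad <- stats::runif(spec$n_background, spec$r_ref, spec$r_bg)
      bg <- dir * rad
    }
    list(X = rbind(ref, bg),
         group = factor(rep(c("reference", "background"),
                            c(spec$n_reference, spec$n_background)),
                        levels = c("reference", "background")))
  })
}

#' Labelled-feature specification (Layer-2 test bed)
#'
#' @param n samples; `d` features; `k_informative` class-shifted columns;
#'   `effect` standardised mean shift between classes; `balance` positive
#'   class fraction; `seed` integer.
#' @return a `labeled_feature_spec`.
#' @export
labeled_feature_spec <- function(n = 200L, d = 1000L, k_informative = 5L,
                                 effect = 2, balance = 0.5, seed = 1L) {
  stopifnot(k_informative <= d, effect >= 0, balance > 0, balance < 1)
  structure(list(n = as.integer(n), d = as.integer(d),
                 k_informative = as.integer(k_informative), effect = effect,
                 balance = balance, seed = as.integer(seed)),
            class = "labeled_feature_spec")
}

#' Generate a labelled feature matrix with planted signal
#'
#' Informative columns are standard Gaussians shifted by `effect` in the
#' positive class; all other columns are pure noise. Ground-truth informative
#' indices are returned for recovery tests.
#'
#' @param spec a [labeled_feature_spec()].
#' @return list: `X`, `y` (0/1), `informative` (integer indices).
#' @export
generate_labeled_features <- function(spec) {
  stopifnot(inherits(spec, "labeled_feature_spec"))
  with_seed(spec$seed, {
    n1 <- round(spec$n * spec$balance)
    y <- sample(rep(c(1L, 0L), c(n1, spec$n - n1)))
    X <- matrix(stats::rnorm(spec$n * spec$d), spec$n, spec$d)
    info <- sort(sample.int(spec$d, spec$k_informative))
    X[, info] <- X[, info] + spec$effect * y
    list(X = X, y = y, informative = info)
  })
}
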