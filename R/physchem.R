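#' Per-residue unfolding thermodynamics table
#'
#' Loads the packaged additive-model constants (per-residue enthalpy and
#' entropy of unfolding). The shipped file is a labelled synthetic stand-in
#' with the correct model structure; supply `path` to use experimentally
#' derived constants with the same schema (`residue,dH_kJ_mol,dS_kJ_mol_K`).
#'
#' @param path optional CSV path overriding the packaged table.
#' @param temperature kelvin; default 298.15.
#' @return A `thermo_tables` list: `dH`, `dS` (named over the 20 residues),
#'   `temperature`.
#' @export
thermo_tables <- function(path = NULL, temperature = 298.15) {
  stopifnot(temperature > 0)
  if (is.null(path))
    path <- system.file("extdata", "thermo_unfolding_synthetic.csv",
                        package = "abtriage", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  if (!setequal(tab$residue, AA20))
    ab_stop("ab_parse_error", "thermo table must cover exactly the 20 standard residues")
  structure(list(dH = stats::setNames(tab$dH_kJ_mol, tab$residue),
                 dS = stats::setNames(tab$dS_kJ_mol_K, tab$residue),
                 temperature = temperature),
            class = "thermo_tables")
}

#' Charge-model parameters for isoelectric-point calculation
#'
#' pKa values (EMBOSS set) for the chain termini and the ionizable side
#' chains, plus the iteration contract: start at pH 6.5 and stop when the net
#' charge is 0 +/- `tolerance`.
#'
#' @param path optional CSV override (`group,pka,sign`).
#' @param start_ph,tolerance,max_iterations solver contract.
#' @return A `pi_params` list.
#' @export
pi_params <- function(path = NULL, start_ph = 6.5, tolerance = 0.01,
                      max_iterations = 200L) {
  stopifnot(tolerance > 0, max_iterations >= 1)
  if (is.null(path))
    path <- system.file("extdata", "pka_emboss.csv",
                        package = "abtriage", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(tab$pka > 0 & tab$pka < 14),
            all(c("Nterm", "Cterm") %in% tab$group))
  structure(list(pka = stats::setNames(tab$pka, tab$group),
                 sign = stats::setNames(tab$sign, tab$group),
                 start_ph = start_ph, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "pi_params")
}

check_alphabet <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  bad <- setdiff(ch, AA20)
  if (length(bad))
    ab_stop("ab_unknown_residue",
            paste("non-standard residue code(s):", paste(unique(bad), collapse = ", ")))
  ch
}

#' Additive unfolding free energy of a sequence
#'
#' Sum over residues of (dH_i - T * dS_i), kJ/mol. The model is strictly
#' additive (no end corrections), so `delta_g_unfolding(paste0(s, t))` equals
#' the sum over the parts; the empty string gives 0.
#'
#' @param seq amino-acid string (may be empty, or a heavy+light concatenation).
#' @param tables a [thermo_tables()].
#' @return numeric scalar, kJ/mol.
#' @export
delta_g_unfolding <- function(seq, tables = thermo_tables()) {
  stopifnot(inherits(tables, "thermo_tables"))
  if (!nzchar(seq)) return(0)
  ch <- check_alphabet(seq)
  sum(tables$dH[ch] - tables$temperature * tables$dS[ch])
}

#' Net charge of a sequence at a given pH
#'
#' Henderson-Hasselbalch sum over the two termini and the ionizable side
#' chains (C, D, E, H, K, R, Y).
#'
#' @param seq amino-acid string.
#' @param ph pH value.
#' @param params a [pi_params()].
#' @return numeric net charge.
#' @export
net_charge <- function(seq, ph, params = pi_params()) {
  ch <- check_alphabet(seq)
  counts <- c(Nterm = 1, Cterm = 1, table(ch)[intersect(names(params$pka), ch)])
  q <- 0
  for (g in names(counts)) {
    if (!g %in% names(params$pka)) next
    pka <- params$pka[[g]]
    q <- q + if (params$sign[[g]] == "positive")
      counts[[g]] / (1 + 10^(ph - pka))
    else
      -counts[[g]] / (1 + 10^(pka - ph))
  }
  q
}

#' Isoelectric point of a sequence
#'
#' Finds the pH at which the net charge is zero within `params$tolerance`
#' (default 0.01 charge units), starting from pH 6.5 and moving up when the
#' charge is positive and down when negative. Implemented as a guarded
#' bisection on (0, 14) -- same contract as the fixed-step iteration, with
#' guaranteed convergence since the charge is monotone decreasing in pH.
#'
#' @inheritParams net_charge
#' @param params a [pi_params()].
#' @return pH at the isoelectric point.
#' @export
isoelectric_point <- function(seq, params = pi_params()) {
  stopifnot(inherits(params, "pi_params"))
  lo <- 0; hi <- 14; ph <- params$start_ph
  for (i in seq_len(params$max_iterations)) {
    q <- net_charge(seq, ph, params)
    # bisect to the charge-neutral pH itself (not merely the first pH whose
    # charge clears the tolerance, which for short peptides can be far from
    # the true root); the |q| <= tolerance contract holds at the root.
    if (abs(q) <= params$tolerance && (hi - lo) < 1e-3) return(ph)
    if (q > 0) lo <- ph else hi <- ph
    ph <- (lo + hi) / 2
  }
  ab_stop("ab_nonconvergence", sprintf(
    "pI iteration did not reach |charge| <= %g in %d steps",
    params$tolerance, params$max_iterations))
}

#' CDR-H3 loop length
#'
#' Residue count in the H95-H102 window (insertions included) of a numbered
#' heavy chain.
#'
#' @param heavy a heavy `numbered_chain` (or [chain_sequence()], numbered here).
#' @return integer length.
#' @export
cdr_h3_length <- function(heavy) {
  if (inherits(heavy, "chain_sequence")) heavy <- number_chain(heavy)
  nchar(extract_cdr(heavy, loop = "H3"))
}

#' Cysteine-count hard filter
#'
#' Chains with more than two cysteines carry an aggregation liability and are
#' excluded. Applied per chain (a normal variable domain has exactly the two
#' conserved cysteines); set `scope = "cdr_h3"` to count only within CDR-H3.
#'
#' @param chain a [chain_sequence()], `numbered_chain`, or plain string.
#' @param scope `"chain"` (default) or `"cdr_h3"`.
#' @return list with `pass` (logical) and `count`.
#' @export
cysteine_filter <- function(chain, scope = c("chain", "cdr_h3")) {
  scope <- match.arg(scope)
  seq <- if (is.character(chain)) chain
         else if (inherits(chain, "numbered_chain")) chain_residues(chain)
         else chain$residues
  if (scope == "cdr_h3") {
    nc <- if (inherits(chain, "numbered_chain")) chain
          else number_chain(chain)
    seq <- extract_cdr(nc, loop = "H3")
  }
  n <- sum(strsplit(seq, "")[[1]] == "C")
  list(pass = n <= 2L, count = n)
}

#' Mean isoelectric point of a heavy/light pair
#'
#' Arithmetic mean of the two chain pI values (default); `method = "concat"`
#' instead computes the pI of the concatenated heavy+light sequence.
#'
#' @param vh,vl amino-acid strings or [chain_sequence()]s.
#' @param params a [pi_params()].
#' @param method `"mean"` or `"concat"`.
#' @return pH value.
#' @export
mean_pair_pi <- function(vh, vl, params = pi_params(),
                         method = c("mean", "concat")) {
  method <- match.arg(method)
  s <- function(x) if (is.character(x)) x else x$residues
  if (method == "concat")
    return(isoelectric_point(paste0(s(vh), s(vl)), params))
  (isoelectric_point(s(vh), params) + isoelectric_point(s(vl), params)) / 2
}

# Feature extraction ------------------------------------------------------

PCF_FEATURES <- c("cdr_h3_length", "dG_vh", "dG_vl", "dG_concat", "mean_pI")

#' Physicochemical feature vector for one paired antibody
#'
#' @param record a [paired_antibody()].
#' @param tables,params constant tables.
#' @param heavy_numbered optional pre-computed numbering (reused if given).
#' @return named numeric vector over
#'   `cdr_h3_length, dG_vh, dG_vl, dG_concat, mean_pI`.
#' @export
physchem_features <- function(record, tables = thermo_tables(),
                              params = pi_params(), heavy_numbered = NULL) {
  stopifnot(inherits(record, "paired_antibody"))
  if (is.null(heavy_numbered)) heavy_numbered <- number_chain(record$heavy)
  vh <- record$heavy$residues; vl <- record$light$residues
  c(cdr_h3_length = cdr_h3_length(heavy_numbered),
    dG_vh = delta_g_unfolding(vh, tables),
    dG_vl = delta_g_unfolding(vl, tables),
    dG_concat = delta_g_unfolding(paste0(vh, vl), tables),
    mean_pI = mean_pair_pi(vh, vl, params))
}

#' Reference means and standard deviations for the Z-score pre-filter
#'
#' @param records list of [paired_antibody()] (>= 2 numberable records).
#' @param tables,params constant tables.
#' @return A `reference_stats` object: `mean`, `sd` (sample, n-1) per feature,
#'   and `n` (records used). Unnumberable records are dropped with a warning.
#' @export
reference_stats <- function(records, tables = thermo_tables(),
                            params = pi_params()) {
  feats <- list(); dropped <- 0L
  for (r in records) {
    f <- tryCatch(physchem_features(r, tables, params),
                  ab_error = function(e) NULL)
    if (is.null(f)) dropped <- dropped + 1L else feats[[length(feats) + 1L]] <- f
  }
  if (dropped) warning(sprintf("reference_stats: dropped %d unnumberable record(s)", dropped))
  if (length(feats) < 2L)
    ab_stop("ab_insufficient_data", "need >= 2 numberable reference records")
  m <- do.call(rbind, feats)
  structure(list(mean = colMeans(m), sd = apply(m, 2, stats::sd),
                 n = nrow(m)), class = "reference_stats")
}

#' Z thresholds for the physicochemical pre-filter
#'
#' @param z default Z applied to every feature (paper default 2).
#' @param off character vector of feature names to disable (or `"all"`).
#' @return named vector over the five features; `NA` = feature off.
#' @export
stage_thresholds <- function(z = 2, off = character(0)) {
  stopifnot(is.numeric(z), z >= 0)
  th <- stats::setNames(rep(z, length(PCF_FEATURES)), PCF_FEATURES)
  if (identical(off, "all")) off <- PCF_FEATURES
  th[off] <- NA_real_
  th
}

#' Physicochemical pre-filter decision for one record
#'
#' Retains the record iff every active feature lies within Z standard
#' deviations of the reference mean, and neither chain fails the cysteine
#' rule. Failures are decisions, not errors: each failing feature is named.
#'
#' @param record a [paired_antibody()].
#' @param stats a [reference_stats()].
#' @param thresholds a [stage_thresholds()] vector.
#' @param tables,params constant tables.
#' @param heavy_numbered optional pre-computed heavy numbering.
#' @return list: `retained` (logical), `reasons` (character), `features`.
#' @export
physchem_filter <- function(record, stats, thresholds = stage_thresholds(),
                            tables = thermo_tables(), params = pi_params(),
                            heavy_numbered = NULL) {
  stopifnot(inherits(stats, "reference_stats"))
  f <- physchem_features(record, tables, params, heavy_numbered)
  reasons <- character(0)
  for (nm in PCF_FEATURES) {
    z <- thresholds[[nm]]
    if (is.na(z)) next
    if (abs(f[[nm]] - stats$mean[[nm]]) > z * stats$sd[[nm]])
      reasons <- c(reasons, nm)
  }
  for (side in c("heavy", "light")) {
    cf <- cysteine_filter(record[[side]])
    if (!cf$pass) reasons <- c(reasons, paste0("cysteine_", side))
  }
  list(retained = length(reasons) == 0L, reasons = reasons, features = f)
}

#' Two-tailed unpaired Mann-Whitney U test
#'
#' Exact enumeration of the U null distribution when the combined sample size
#' is at most 12 (ties handled by midranks); otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with `U` (statistic for `a`) and `p` (two-tailed).
#' @export
compare_groups <- function(a, b) {
  if (!length(a) || !length(b))
    ab_stop("ab_degenerate_input", "both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  v <- c(a, b)
  rk <- rank(v)                       # midranks for ties
  u_of <- function(idx) sum(rk[idx]) - length(idx) * (length(idx) + 1) / 2
  U <- u_of(seq_len(na))
  if (n <= 12L) {
    combs <- utils::combn(n, na)
    us <- apply(combs, 2, u_of)
    u_lo <- min(U, na * nb - U)
    p <- min(1, 2 * mean(us <= u_lo + 1e-9))
  } else {
    mu <- na * nb / 2
    ties <- table(v)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p = p)
}
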