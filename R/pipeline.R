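# Pipeline orchestration: paired I/O, stage composition (physicochemical
# pre-filter -> number/encode -> Layer 1 -> Layer 2) and TSV/JSON reporting.
# Stage order is fixed: the cheap sequence filters run before any encoding.

#' Construct a paired antibody record
#'
#' @param id unique identifier.
#' @param heavy,light amino-acid strings (or [chain_sequence()]s).
#' @param status optional label: `approved`, `discontinued`, `clinical`,
#'   `library`, or `query`.
#' @param light_type optional `"kappa"`/`"lambda"` annotation.
#' @return a `paired_antibody`.
#' @export
paired_antibody <- function(id, heavy, light, status = NA_character_,
                            light_type = NA_character_) {
  h <- if (inherits(heavy, "chain_sequence")) heavy
       else chain_sequence(id, "heavy", heavy)
  l <- if (inherits(light, "chain_sequence")) light
       else chain_sequence(id, "light", light)
  structure(list(id = as.character(id), heavy = h, light = l,
                 status = status, light_type = light_type),
            class = "paired_antibody")
}

#' @export
print.paired_antibody <- function(x, ...) {
  cat(sprintf("<paired_antibody> %s: VH %d aa, VL %d aa%s\n", x$id,
              nchar(x$heavy$residues), nchar(x$light$residues),
              if (is.na(x$status)) "" else paste0(" [", x$status, "]")))
  invisible(x)
}

#' Read paired antibodies from FASTA or CSV
#'
#' FASTA records pair by identifier stem with `/H`+`/L` (or `_VH`+`_VL`)
#' suffixes; unpaired or duplicated ids are skipped with a warning and listed
#' in the `"skipped"` attribute. CSV needs columns `id`, `sequence_heavy`,
#' `sequence_light` and may carry `status` and `light_type`.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"`, or `"csv"`.
#' @return list of [paired_antibody()].
#' @export
read_paired <- function(path, format = c("auto", "fasta", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) ab_stop("ab_parse_error", paste("no such file:", path))
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "csv"
  if (format == "fasta") {
    ss <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) ab_stop("ab_parse_error", conditionMessage(e)))
    ids <- sub("\\s.*", "", names(ss))
    suf <- ifelse(grepl("(/H|_VH)$", ids), "H",
                  ifelse(grepl("(/L|_VL)$", ids), "L", NA))
    stem <- sub("(/H|/L|_VH|_VL)$", "", ids)
    skipped <- character(0); out <- list()
    for (s in unique(stem)) {
      hi <- which(stem == s & suf == "H"); li <- which(stem == s & suf == "L")
      if (length(hi) != 1L || length(li) != 1L) {
        skipped <- c(skipped, s); next
      }
      rec <- tryCatch(paired_antibody(s, as.character(ss[[hi]]),
                                      as.character(ss[[li]])),
                      ab_error = function(e) NULL)
      if (is.null(rec)) skipped <- c(skipped, s) else out[[s]] <- rec
    }
  } else {
    tab <- tryCatch(utils::read.csv(path, colClasses = "character"),
                    error = function(e) ab_stop("ab_parse_error", conditionMessage(e)))
    need <- c("id", "sequence_heavy", "sequence_light")
    if (!all(need %in% names(tab)))
      ab_stop("ab_parse_error", paste("CSV must have columns:",
                                      paste(need, collapse = ", ")))
    skipped <- character(0); out <- list()
    for (i in seq_len(nrow(tab))) {
      id <- tab$id[i]
      if (id %in% names(out)) { skipped <- c(skipped, id); next }
      rec <- tryCatch(paired_antibody(
        id, tab$sequence_heavy[i], tab$sequence_light[i],
        status = if ("status" %in% names(tab)) tab$status[i] else NA_character_,
        light_type = if ("light_type" %in% names(tab)) tab$light_type[i]
                     else NA_character_),
        ab_error = function(e) NULL)
      if (is.null(rec)) skipped <- c(skipped, id) else out[[id]] <- rec
    }
  }
  if (length(skipped))
    warning(sprintf("read_paired: skipped %d record(s): %s", length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")))
  structure(unname(out), skipped = skipped)
}

#' Write paired antibodies to CSV
#' @param records list of [paired_antibody()].
#' @param path output CSV path.
#' @export
write_paired_csv <- function(records, path) {
  tab <- data.frame(
    id = vapply(records, `[[`, "", "id"),
    sequence_heavy = vapply(records, function(r) r$heavy$residues, ""),
    sequence_light = vapply(records, function(r) r$light$residues, ""),
    status = vapply(records, function(r) as.character(r$status), ""),
    light_type = vapply(records, function(r) as.character(r$light_type), ""))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract heavy/light pairs from a per-cell BCR chain table
#'
#' One pair per barcode carrying an IGH chain and at least one light chain;
#' when both IGK and IGL are present the light chain with the highest count
#' wins, ties broken by first occurrence. Unpairable barcodes are counted in
#' the `"unpaired"` attribute.
#'
#' @param cells data.frame with columns `barcode`, `locus` (IGH/IGK/IGL),
#'   `sequence`, `count`.
#' @return list of [paired_antibody()].
#' @export
extract_bcr_pairs <- function(cells) {
  need <- c("barcode", "locus", "sequence", "count")
  if (!all(need %in% names(cells)))
    ab_stop("ab_parse_error", paste("cell table must have columns:",
                                    paste(need, collapse = ", ")))
  out <- list(); unpaired <- 0L
  for (bc in unique(cells$barcode)) {
    sub <- cells[cells$barcode == bc, , drop = FALSE]
    h <- sub[sub$locus == "IGH", , drop = FALSE]
    l <- sub[sub$locus %in% c("IGK", "IGL"), , drop = FALSE]
    if (nrow(h) == 0L || nrow(l) == 0L) { unpaired <- unpaired + 1L; next }
    h <- h[which.max(h$count), ]
    l <- l[which.max(l$count), ]        # which.max: first occurrence on ties
    rec <- tryCatch(paired_antibody(
      bc, h$sequence, l$sequence,
      light_type = if (l$locus == "IGK") "kappa" else "lambda"),
      ab_error = function(e) NULL)
    if (is.null(rec)) unpaired <- unpaired + 1L else out[[bc]] <- rec
  }
  structure(unname(out), unpaired = unpaired)
}

#' Pipeline configuration
#'
#' Every stage can be turned off; all randomness flows from `seed` via named
#' substreams. `gamma = NULL` uses the 1/n_features kernel default (the
#' published gamma = 500 applies to the real language-model encodings).
#'
#' @param pcf_z Z for the physicochemical pre-filter (`"off"` disables).
#' @param pcf_off feature names excluded from the pre-filter.
#' @param layer1_z ellipse Z: positive number, `"all"`, or `"off"`.
#' @param layer2_threshold probability threshold (`"off"` disables Layer 2).
#' @param layer2_k features selected for the classifier.
#' @param classifier `"linear_margin"`, `"ridge"`, or `"logistic"`.
#' @param encoder encoder name or an `encoder` object.
#' @param encoder_dim,encoder_seed mock-encoder parameters.
#' @param kernel,gamma kernel PCA settings.
#' @param frozen_fit fit the projection on library+clinical only (excludes
#'   the query; restores gate monotonicity across reruns).
#' @param max_library library subsample cap for the kernel fit.
#' @param seed global seed.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(pcf_z = 2, pcf_off = character(0),
                            layer1_z = "all", layer2_threshold = 0.5,
                            layer2_k = 2500L, classifier = "linear_margin",
                            encoder = "mock", encoder_dim = 8L,
                            encoder_seed = 42L, kernel = "rbf", gamma = NULL,
                            frozen_fit = FALSE, max_library = 10000L,
                            seed = 1L) {
  structure(list(pcf_z = pcf_z, pcf_off = pcf_off, layer1_z = layer1_z,
                 layer2_threshold = layer2_threshold,
                 layer2_k = as.integer(layer2_k), classifier = classifier,
                 encoder = encoder, encoder_dim = as.integer(encoder_dim),
                 encoder_seed = as.integer(encoder_seed), kernel = kernel,
                 gamma = gamma, frozen_fit = isTRUE(frozen_fit),
                 max_library = as.integer(max_library),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_fail <- function(stage, e)
  stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
       call. = FALSE)

#' Run the full triaging pipeline
#'
#' Stages in fixed order: numbering (records that fail are excluded up
#' front), physicochemical Z-filter against the approved reference stats
#' (falling back to the clinical set), one-time encoding, the Layer-1
#' kernel-PCA ellipse gate (fit on library + clinical + query, or frozen to
#' library + clinical), and the Layer-2 classifier trained on the
#' approved/discontinued reference sets (or a prefitted model).
#'
#' @param query list of [paired_antibody()].
#' @param reference named list with any of `clinical`, `library`, `approved`,
#'   `discontinued` (each a list of records), and optionally `layer2_model` +
#'   `layer2_selection` for a prefitted Layer 2.
#' @param config a [pipeline_config()].
#' @return a `triage_report`: `header` (run metadata, stage survivor counts)
#'   and `rows` (one per input id with per-stage verdicts).
#' @export
run_pipeline <- function(query, reference = list(), config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ids <- vapply(query, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("query ids must be unique")
  pcf_on <- !identical(config$pcf_z, "off")
  l1_on <- !identical(config$layer1_z, "off")
  l2_on <- !identical(config$layer2_threshold, "off")

  rows <- data.frame(id = ids, numberable = NA, pcf_retained = NA,
                     pcf_reasons = "", layer1_inside = NA,
                     pc1 = NA_real_, pc2 = NA_real_,
                     layer2_probability = NA_real_, layer2_label = "",
                     final = "", stringsAsFactors = FALSE)

  # numbering (once; reused by every later stage)
  numbered <- list()
  for (r in query) {
    nb <- tryCatch(list(h = number_chain(r$heavy), l = number_chain(r$light)),
                   ab_error = function(e) conditionMessage(e))
    if (is.character(nb)) {
      rows$numberable[rows$id == r$id] <- FALSE
      rows$final[rows$id == r$id] <- "rejected:numbering"
    } else {
      rows$numberable[rows$id == r$id] <- TRUE
      numbered[[r$id]] <- nb
    }
  }
  alive <- names(numbered)
  survivors <- c(input = length(ids), numbering = length(alive))

  # physicochemical pre-filter
  if (pcf_on && length(alive)) {
    ref_set <- if (length(reference$approved)) reference$approved
               else reference$clinical
    stats <- tryCatch(reference_stats(ref_set),
                      error = function(e) stage_fail("pcf", e))
    th <- stage_thresholds(config$pcf_z, config$pcf_off)
    for (id in alive) {
      r <- query[[which(ids == id)]]
      v <- physchem_filter(r, stats, th, heavy_numbered = numbered[[id]]$h)
      i <- which(rows$id == id)
      rows$pcf_retained[i] <- v$retained
      rows$pcf_reasons[i] <- paste(v$reasons, collapse = ";")
      if (!v$retained) rows$final[i] <- "rejected:pcf"
    }
    alive <- alive[rows$pcf_retained[match(alive, rows$id)]]
  }
  survivors["pcf"] <- length(alive)

  # one-time encoding of everything the ML layers need
  enc <- if (inherits(config$encoder, "encoder")) config$encoder
         else get_encoder(config$encoder, dim = config$encoder_dim,
                          seed = config$encoder_seed)
  # the numbering cache belongs to the query set only: reference sets may
  # legitimately reuse identifiers, so they are always numbered afresh
  encode_set <- function(recs, use_cache = FALSE) {
    rows_ <- lapply(recs, function(r) {
      nb <- if (use_cache) numbered[[r$id]]
      if (is.null(nb)) nb <- list(h = number_chain(r$heavy),
                                  l = number_chain(r$light))
      encode_pair(pad_pair(nb$h, nb$l, enc$spec$pad_char), enc)
    })
    m <- do.call(rbind, rows_)
    rownames(m) <- vapply(recs, `[[`, "", "id")
    m
  }
  Xq <- NULL
  if ((l1_on || l2_on) && length(alive))
    Xq <- tryCatch(encode_set(query[match(alive, ids)], use_cache = TRUE),
                   error = function(e) stage_fail("encoding", e))

  # Layer 1: kernel PCA + ellipse gate
  if (l1_on && length(alive)) {
    if (length(reference$clinical) < 3)
      stage_fail("layer1", simpleError(
        "need >= 3 numberable clinical reference records"))
    Xc <- tryCatch(encode_set(reference$clinical),
                   error = function(e) stage_fail("layer1", e))
    Xl <- if (length(reference$library)) encode_set(reference$library)
          else NULL
    if (!is.null(Xl) && nrow(Xl) > config$max_library) {
      keep <- with_seed(config$seed + 1L,
                        sample.int(nrow(Xl), config$max_library))
      Xl <- Xl[keep, , drop = FALSE]
    }
    fit_X <- rbind(Xl, Xc, if (!config$frozen_fit) Xq)
    model <- tryCatch({
      cfg <- kpca_config(config$kernel,
                         gamma = if (is.null(config$gamma)) 1 / ncol(fit_X)
                                 else config$gamma)
      fit_kpca(fit_X, cfg)
    }, error = function(e) stage_fail("layer1", e))
    pc <- kpca_project(model, Xc)
    pq <- kpca_project(model, Xq)
    e <- tryCatch(ellipse_from_reference(pc, config$layer1_z),
                  error = function(e) stage_fail("layer1", e))
    inside <- point_in_ellipse(e, pq)
    i <- match(alive, rows$id)
    rows$layer1_inside[i] <- inside
    rows$pc1[i] <- pq[, 1]; rows$pc2[i] <- pq[, 2]
    rows$final[i][!inside] <- "rejected:layer1"
    alive <- alive[inside]
    Xq <- Xq[inside, , drop = FALSE]
  }
  survivors["layer1"] <- length(alive)

  # Layer 2: supervised approved-vs-discontinued classifier
  if (l2_on && length(alive)) {
    if (!is.null(reference$layer2_model)) {
      model <- reference$layer2_model
      sel <- reference$layer2_selection
    } else if (length(reference$approved) >= 2 &&
               length(reference$discontinued) >= 2) {
      Xa <- encode_set(reference$approved)
      Xd <- encode_set(reference$discontinued)
      Xt <- rbind(Xa, Xd)
      yt <- rep(c(1L, 0L), c(nrow(Xa), nrow(Xd)))
      sel <- select_k(f_regression_rank(Xt, yt), config$layer2_k)
      model <- train_classifier(Xt[, sel$indices, drop = FALSE], yt,
                                kind = config$classifier, seed = config$seed,
                                threshold = if (is.numeric(config$layer2_threshold))
                                  config$layer2_threshold else 0.5)
    } else {
      stage_fail("layer2", simpleError(
        "need approved and discontinued reference sets (or a prefitted model)"))
    }
    pr <- predict(model, Xq[, sel$indices, drop = FALSE],
                  threshold = config$layer2_threshold)
    i <- match(alive, rows$id)
    rows$layer2_probability[i] <- pr$probability
    rows$layer2_label[i] <- pr$label
    rej <- pr$label != "approved"
    rows$final[i][rej] <- "rejected:layer2"
    alive <- alive[!rej]
  }
  survivors["layer2"] <- length(alive)

  rows$final[rows$final == ""] <- "retained"
  structure(list(
    header = list(
      package = "abtriage", seed = config$seed,
      encoder = enc$spec$name, encoder_dim = enc$spec$dim,
      pcf_z = as.character(config$pcf_z),
      layer1_z = as.character(config$layer1_z),
      layer2_threshold = as.character(config$layer2_threshold),
      frozen_fit = config$frozen_fit,
      n_query = length(ids),
      n_reference = vapply(reference[intersect(names(reference),
        c("clinical", "library", "approved", "discontinued"))], length, 0L),
      survivors = survivors),
    rows = rows), class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  s <- x$header$survivors
  cat("<triage_report>\n ",
      paste(sprintf("%s=%d", names(s), s), collapse = " -> "), "\n")
  invisible(x)
}

#' Write a triage report (TSV body + JSON run header)
#'
#' Byte-stable for identical reports: numeric columns are fixed-format.
#'
#' @param report a `triage_report`.
#' @param path TSV output path; the header goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "triage_report"))
  rows <- report$rows
  for (cl in c("pc1", "pc2", "layer2_probability"))
    rows[[cl]] <- ifelse(is.na(rows[[cl]]), "NA", sprintf("%.6g", rows[[cl]]))
  ok <- tryCatch({
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report$header, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) ab_stop("ab_parse_error", paste("could not write report to", path))
  invisible(path)
}
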