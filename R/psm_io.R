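#' Paired top/second PSM score dataset
#'
#' Container for one pair of scores per spectrum: the top-ranked PSM score
#' `s1` and the second-ranked score `s2`, which may be missing (`NA`) when
#' the search produced a single eligible candidate. The fraction of spectra
#' with missing second scores, `v_phi`, is carried along because it enters
#' the mixing-weight constraints as a constant.
#'
#' @param s1 numeric vector of top scores.
#' @param s2 numeric vector of second scores; `NA` marks missing. When `s2`
#'   is present it must not exceed its `s1` (unless `check_order = FALSE`,
#'   used by samplers that draw the two marginals independently).
#' @param check_order enforce the within-spectrum ordering `s2 <= s1`.
#' @return An object of class `"score_dataset"`: a data frame with columns
#'   `s1`, `s2` and attribute `v_phi`.
#' @export
score_dataset <- function(s1, s2 = rep(NA_real_, length(s1)),
                          check_order = TRUE) {
  stopifnot(is.numeric(s1), length(s1) == length(s2))
  s2 <- as.numeric(s2)
  if (anyNA(s1)) stop("'s1' must not contain missing values")
  bad <- which(!is.na(s2) & s2 > s1 + 1e-12)
  if (check_order && length(bad))
    stop("second score exceeds top score at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  ds <- data.frame(s1 = as.numeric(s1), s2 = s2)
  attr(ds, "v_phi") <- if (nrow(ds)) mean(is.na(s2)) else NA_real_
  class(ds) <- c("score_dataset", "data.frame")
  ds
}

#' Proportion of spectra with missing second scores
#'
#' @param ds a [score_dataset()].
#' @return The exact fraction of records whose `s2` is missing.
#' @export
compute_v_phi <- function(ds) {
  stopifnot(inherits(ds, "score_dataset"))
  if (nrow(ds) == 0L) stop("empty dataset")
  fixed <- attr(ds, "v_phi_fixed")   # binned representations carry the
  if (!is.null(fixed)) return(fixed) # original proportion
  mean(is.na(ds$s2))
}

#' @export
print.score_dataset <- function(x, ...) {
  cat(sprintf("score_dataset: %d spectra, v_phi = %.4f\n",
              nrow(x), compute_v_phi(x)))
  invisible(x)
}

#' Extract top-two scores per spectrum from a ranked PSM table
#'
#' Applies the top-two extraction rules: for each spectrum keep the
#' top-ranked score as `s1`; if the rank-1 and rank-2 candidates share the
#' same peptide pair but differ only in the cross-link residue position,
#' drop rank 2 and promote rank 3 (if available) to the second position.
#' A spectrum with a single eligible candidate gets `s2 = NA`.
#'
#' @param records a data frame with columns `spectrum_id`,
#'   `peptide_pair_id`, `xl_position_id`, `rank`, `score` (as produced by
#'   [read_ranked_tsv()]). If `rank` is absent, candidates are ordered by
#'   score descending with stable ties on `peptide_pair_id`.
#' @return A [score_dataset()] with one row per spectrum, ordered by
#'   spectrum id.
#' @export
extract_top_two <- function(records) {
  needed <- c("spectrum_id", "peptide_pair_id", "xl_position_id", "score")
  if (!all(needed %in% names(records)))
    stop("ranked PSM table needs columns: ",
         paste(needed, collapse = ", "))
  if (nrow(records) == 0L)
    return(score_dataset(numeric(0), numeric(0)))
  if (!"rank" %in% names(records)) {
    ord <- order(records$spectrum_id, -records$score, records$peptide_pair_id)
    records <- records[ord, , drop = FALSE]
    records$rank <- stats::ave(records$score, records$spectrum_id,
                               FUN = seq_along)
  }
  key <- paste(records$spectrum_id, records$rank, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (spectrum_id, rank) entries in ranked PSM table")
  parts <- split(records[order(records$spectrum_id, records$rank),
                         , drop = FALSE],
                 records$spectrum_id[order(records$spectrum_id,
                                           records$rank)])
  res <- lapply(parts, function(g) {
    if (g$rank[1L] != 1L)
      stop("spectrum ", g$spectrum_id[1L], " has no rank-1 PSM")
    s1 <- g$score[1L]
    s2 <- NA_real_
    if (nrow(g) >= 2L) {
      same_pair <- g$peptide_pair_id[2L] == g$peptide_pair_id[1L] &&
        g$xl_position_id[2L] != g$xl_position_id[1L]
      if (same_pair) {
        if (nrow(g) >= 3L) s2 <- g$score[3L]
      } else {
        s2 <- g$score[2L]
      }
    }
    c(s1 = s1, s2 = s2)
  })
  m <- do.call(rbind, res)
  score_dataset(m[, "s1"], m[, "s2"])
}

#' Read a paired (wide-form) score table
#'
#' Expects a tab-separated file with header `s1`, `s2`; an empty field or
#' `NA` in `s2` marks a missing second score.
#'
#' @param path file path.
#' @param check_order enforce the within-spectrum ordering `s2 <= s1`
#'   (disable for idealized simulated data with independent marginals).
#' @return A [score_dataset()].
#' @export
read_scores_tsv <- function(path, check_order = TRUE) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = c("", "NA"),
                           colClasses = NA, check.names = FALSE)
  if (!all(c("s1", "s2") %in% names(tab)))
    stop("wide-form score TSV must have columns 's1' and 's2'")
  s1 <- suppressWarnings(as.numeric(tab$s1))
  s2 <- suppressWarnings(as.numeric(tab$s2))
  bad <- which(is.na(s1) | (!is.na(tab$s2) & is.na(s2)))
  if (length(bad))
    stop("malformed score value at data line ", bad[1L], " of ", path)
  score_dataset(s1, s2, check_order = check_order)
}

#' Read a ranked (long-form) PSM table
#'
#' Expects a tab-separated file with header `spectrum_id`,
#' `peptide_pair_id`, `xl_position_id`, `rank`, `score`.
#'
#' @param path file path.
#' @return A data frame of ranked PSM records suitable for
#'   [extract_top_two()].
#' @export
read_ranked_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  needed <- c("spectrum_id", "peptide_pair_id", "xl_position_id",
              "rank", "score")
  if (!all(needed %in% names(tab)))
    stop("ranked PSM TSV must have columns: ", paste(needed, collapse = ", "))
  rank <- suppressWarnings(as.integer(tab$rank))
  score <- suppressWarnings(as.numeric(tab$score))
  bad <- which(is.na(rank) | is.na(score))
  if (length(bad))
    stop("malformed rank/score at data line ", bad[1L], " of ", path)
  data.frame(spectrum_id = tab$spectrum_id,
             peptide_pair_id = tab$peptide_pair_id,
             xl_position_id = tab$xl_position_id,
             rank = rank, score = score)
}

#' Serialize a fitted mixture model to JSON
#'
#' Writes all component parameters (canonical form), mixing weights, the
#' missing-second-score proportion and fit metadata, losslessly (full double
#' precision).
#'
#' @param model a [two_sample_model()] or [one_sample_model()].
#' @param path output file path.
#' @param meta optional named list of fit metadata (restarts, seed,
#'   iterations, log-likelihood, ...).
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, meta = list()) {
  stopifnot(inherits(model, c("two_sample_model", "one_sample_model")))
  obj <- list(
    kind = if (inherits(model, "two_sample_model")) "two-sample"
           else "one-sample",
    components = lapply(model$theta, function(p)
      list(mu = p$mu, sigma = p$sigma, lambda = p$lambda)),
    w = as.list(model$w),
    v = if (!is.null(model$v)) as.list(model$v) else NULL,
    v_phi = model$v_phi,
    meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a mixture model from JSON
#'
#' @param path file path written by [write_model_json()].
#' @return A [two_sample_model()] or [one_sample_model()], with the stored
#'   metadata attached as attribute `"meta"`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  theta <- lapply(obj$components, function(p)
    sn_params(p$mu, p$sigma, p$lambda))
  names(theta) <- names(obj$components)
  w <- unlist(obj$w)
  model <- if (identical(obj$kind, "two-sample")) {
    two_sample_model(theta, w, unlist(obj$v), obj$v_phi)
  } else {
    one_sample_model(theta, w)
  }
  attr(model, "meta") <- obj$meta
  model
}
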