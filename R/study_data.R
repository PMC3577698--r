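#' Assemble a matched case-control study with contextual categories
#'
#' A study holds subjects nested in matched sets (one case plus one or two
#' controls, matched on a group-level contextual category) nested in
#' categories.  Genotypes are stored as unordered \code{"X/Y"} allele pairs
#' and coded through the manifest's genetic models.
#'
#' @param subjects data frame with columns \code{subject_id}, \code{set_id},
#'   \code{category}, \code{status} (1 = case, 0 = control), one genotype
#'   column per manifest SNP, and any further numeric columns taken as
#'   covariates.
#' @param manifest a \code{\link{snp_manifest}}.
#' @param validate if \code{TRUE} (default), matched-set invariants are
#'   enforced and violations raise an error; with \code{FALSE} the object is
#'   built anyway so that \code{\link{validate_sets}} can report problems.
#' @return An object of class \code{"cgx_study"}: a list with elements
#'   \code{subjects} (the input rows), \code{categories} (id/label table),
#'   \code{sets} (per-set category and size), \code{manifest}, \code{coded}
#'   (n x G integer genotype matrix), \code{covariates} (n x Q numeric
#'   matrix), and index vectors \code{y}, \code{cat_idx}, \code{set_idx}.
#' @seealso \code{\link{read_study_csv}}, \code{\link{validate_sets}}
#' @export
study_data <- function(subjects, manifest, validate = TRUE) {
  required <- c("subject_id", "set_id", "category", "status")
  miss <- setdiff(required, names(subjects))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  miss_snp <- setdiff(manifest$snp_id, names(subjects))
  if (length(miss_snp))
    stop("missing genotype column(s): ", paste(miss_snp, collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop("duplicated subject ids")
  status <- subjects$status
  if (!all(status %in% c(0L, 1L)))
    stop("status must be 0 (control) or 1 (case); offending rows: ",
         paste(which(!(status %in% c(0L, 1L))), collapse = ", "))

  cat_labels <- sort(unique(as.character(subjects$category)))
  categories <- data.frame(id = seq_along(cat_labels), label = cat_labels,
                           stringsAsFactors = FALSE)
  cat_idx <- match(as.character(subjects$category), cat_labels)

  set_ids <- unique(as.character(subjects$set_id))
  set_idx <- match(as.character(subjects$set_id), set_ids)
  set_cat <- vapply(seq_along(set_ids), function(p) {
    cats <- unique(cat_idx[set_idx == p])
    if (length(cats) > 1L) NA_integer_ else cats
  }, 1L)
  sets <- data.frame(
    set_id = set_ids,
    category_id = set_cat,
    n_cases = as.integer(tapply(status, set_idx, sum)),
    n_controls = as.integer(tapply(1L - status, set_idx, sum)),
    stringsAsFactors = FALSE)

  G <- nrow(manifest)
  coded <- matrix(NA_integer_, nrow(subjects), G,
                  dimnames = list(NULL, manifest$snp_id))
  for (g in seq_len(G)) {
    coded[, g] <- code_genotype(subjects[[manifest$snp_id[g]]],
                                manifest$ref[g], manifest$alt[g],
                                manifest$coding[g],
                                snp_id = manifest$snp_id[g],
                                subject_id = subjects$subject_id)
  }

  covar_names <- setdiff(names(subjects), c(required, manifest$snp_id))
  covariates <- matrix(0, nrow(subjects), length(covar_names),
                       dimnames = list(NULL, covar_names))
  for (v in covar_names) {
    x <- subjects[[v]]
    if (!is.numeric(x))
      stop("covariate column '", v, "' is not numeric")
    covariates[, v] <- x
  }

  obj <- structure(list(subjects = as.data.frame(subjects),
                        categories = categories, sets = sets,
                        manifest = manifest, coded = coded,
                        covariates = covariates,
                        y = as.integer(status),
                        cat_idx = cat_idx, set_idx = set_idx),
                   class = "cgx_study")
  if (validate) {
    rep <- validate_sets(obj)
    if (nrow(rep))
      stop("invalid matched sets:\n",
           paste0("  ", rep$set_id, ": ", rep$problem, collapse = "\n"))
    if (anyNA(coded))
      stop("missing genotypes ('./.') present; the default fit does not ",
           "impute - remove or complete these subjects")
  }
  obj
}

#' @export
print.cgx_study <- function(x, ...) {
  cat("Matched case-control study: ", sum(x$y), " cases / ",
      sum(1L - x$y), " controls in ", nrow(x$sets), " sets across ",
      nrow(x$categories), " contextual categories; ",
      nrow(x$manifest), " SNPs\n", sep = "")
  invisible(x)
}

#' Check matched-set invariants
#'
#' Each matched set must contain exactly one case and one or two controls,
#' and all its members must share one contextual category.
#'
#' @param data a \code{"cgx_study"} object.
#' @return A data frame report with columns \code{set_id} and \code{problem};
#'   zero rows when all sets are valid.
#' @export
validate_sets <- function(data) {
  stopifnot(inherits(data, "cgx_study"))
  s <- data$sets
  problems <- list()
  flag <- function(id, why) problems[[length(problems) + 1L]] <<-
    data.frame(set_id = id, problem = why, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(s))) {
    if (is.na(s$category_id[i]))
      flag(s$set_id[i], "mixed category: members span more than one category")
    if (s$n_cases[i] != 1L)
      flag(s$set_id[i], sprintf("case count %d (expected exactly 1)",
                                s$n_cases[i]))
    if (!(s$n_controls[i] %in% c(1L, 2L)))
      flag(s$set_id[i], sprintf("control count out of range: %d (expected 1 or 2)",
                                s$n_controls[i]))
  }
  if (length(problems)) do.call(rbind, problems)
  else data.frame(set_id = character(), problem = character(),
                  stringsAsFactors = FALSE)
}

#' Read a matched case-control study from CSV/TSV
#'
#' The file must have a header with columns
#' \code{subject_id,set_id,category,status}, one column per manifest SNP
#' holding \code{"X/Y"} genotype strings (allele order irrelevant), and
#' optional numeric covariate columns.
#'
#' @param path CSV (or TSV, if \code{sep = "\t"}) file.
#' @param manifest a \code{\link{snp_manifest}}.
#' @param sep field separator.
#' @param validate enforce matched-set invariants (default \code{TRUE}).
#' @return A \code{\link{study_data}} object.
#' @export
read_study_csv <- function(path, manifest, sep = ",", validate = TRUE) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot read study file '", path, "': ",
                             conditionMessage(e)))
  required <- c("subject_id", "set_id", "category", "status")
  miss <- setdiff(c(required, manifest$snp_id), names(df))
  if (length(miss))
    stop("study file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  df$status <- as.integer(df$status)
  covar <- setdiff(names(df), c(required, manifest$snp_id))
  for (v in covar) df[[v]] <- as.numeric(df[[v]])
  study_data(df, manifest, validate = validate)
}

#' Write a study back to CSV
#'
#' Inverse of \code{\link{read_study_csv}} up to column order and genotype
#' allele order.
#'
#' @param data a \code{"cgx_study"} object.
#' @param path output file.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_study_csv <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "cgx_study"))
  utils::write.table(data$subjects, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
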