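#' Marginal genotype counts from the motivating metabolic syndrome study
#'
#' Loads the packaged table of observed genotype-class counts of metabolic
#' syndrome cases and matched controls for five candidate SNPs, broken down
#' by the four categories (I-IV) of residential exercise-facility
#' availability.  These are marginal counts: the study's individual-level
#' pairings were never published, so no subject-level reconstruction is
#' possible from this table.
#'
#' @return A data frame of class \code{"cgx_counts"} with columns
#'   \code{snp_id}, \code{genotype_class}, \code{code}, \code{category},
#'   \code{cases}, \code{controls}.  Attributes \code{case_total} and
#'   \code{control_total} hold the study-wide totals (268 cases, 322
#'   controls), verified against the per-SNP sums at load time.
#'
#' @note Two cells of the published table are internally inconsistent and
#'   are stored here with the unique corrections under which every printed
#'   margin (per-class row totals, per-category column totals, and the
#'   268/322 grand totals) is satisfied: the rs12535708 A/A cell for
#'   category IV prints 3 cases / 4 controls but must be 4/3 (an evident
#'   case/control transposition; the printed row totals are 23/17 and the
#'   category-IV margins 56/71), and the rs7799039 A/A,A/G control count for
#'   category II prints 108 but must be 105 (the printed row total is 281
#'   and the category-II margin 122).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_genotype_counts.csv",
                      package = "cgx", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  per_snp_cases <- tapply(tab$cases, tab$snp_id, sum)
  per_snp_controls <- tapply(tab$controls, tab$snp_id, sum)
  if (length(unique(per_snp_cases)) != 1L ||
      length(unique(per_snp_controls)) != 1L)
    stop("corrupt fixture: per-SNP totals disagree")
  structure(tab,
            case_total = unname(per_snp_cases[1L]),
            control_total = unname(per_snp_controls[1L]),
            class = c("cgx_counts", "data.frame"))
}

#' Crude stratum odds ratio from a marginal counts table
#'
#' Computes the unadjusted 2x2 odds ratio for one genotype class against a
#' reference class within one category stratum:
#' (case_exposed x control_reference) / (control_exposed x case_reference).
#' This is a descriptive quantity; it does not use the matching.
#'
#' @param table a counts table from \code{\link{load_table1_fixture}}.
#' @param snp SNP id.
#' @param category category label (e.g. \code{"I"}).
#' @param exposed_class genotype class treated as exposed (e.g. \code{"C/G"}).
#' @param reference_class genotype class treated as unexposed; defaults to
#'   the stratum's code-0 class.
#' @param haldane if \code{TRUE}, add 0.5 to all four cells
#'   (Haldane-Anscombe correction).  Without it, a zero denominator cell
#'   yields \code{Inf}.
#' @return The odds ratio (a single number).
#' @examples
#' tab <- load_table1_fixture()
#' stratum_odds_ratio(tab, "rs1801282", "I", "C/G")  # (5*52)/(1*46) = 5.65
#' @export
stratum_odds_ratio <- function(table, snp, category, exposed_class,
                               reference_class = NULL, haldane = FALSE) {
  stratum <- table[table$snp_id == snp & table$category == category, ]
  if (!nrow(stratum))
    stop("no counts for SNP ", snp, " in category ", category)
  if (is.null(reference_class))
    reference_class <- stratum$genotype_class[stratum$code == 0L][1L]
  exp_row <- stratum[stratum$genotype_class == exposed_class, ]
  ref_row <- stratum[stratum$genotype_class == reference_class, ]
  if (nrow(exp_row) != 1L || nrow(ref_row) != 1L)
    stop("genotype class not found in stratum: ",
         if (nrow(exp_row) != 1L) exposed_class else reference_class)
  a <- exp_row$cases; b <- exp_row$controls
  c_ <- ref_row$cases; d <- ref_row$controls
  if (a + b + c_ + d == 0L)
    stop("undefined odds ratio: all four cells are zero")
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  if (b * c_ == 0) return(Inf)
  (a * d) / (b * c_)
}
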