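#' SNP manifest: alleles and genetic coding per SNP
#'
#' A manifest declares, for each SNP, its reference and alternative allele and
#' the genetic model used to code genotypes into integers: \code{"additive"}
#' (count of alternative alleles, 0/1/2), \code{"dominant"} (carrier of at
#' least one alternative allele, 0/1) or \code{"recessive"} (homozygous
#' alternative, 0/1).
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param ref,alt character vectors of reference / alternative alleles.
#' @param coding character vector, each one of \code{"additive"},
#'   \code{"dominant"}, \code{"recessive"}.
#' @return A data frame of class \code{"cgx_manifest"} with columns
#'   \code{snp_id}, \code{ref}, \code{alt}, \code{coding} and the derived
#'   \code{max_code} (2 for additive, 1 otherwise).
#' @examples
#' snp_manifest("rs1801282", "C", "G", "additive")
#' @export
snp_manifest <- function(snp_id, ref, alt, coding) {
  coding <- match.arg(coding, c("additive", "dominant", "recessive"),
                      several.ok = TRUE)
  if (anyDuplicated(snp_id))
    stop("duplicated SNP ids in manifest: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  m <- data.frame(snp_id = as.character(snp_id),
                  ref = as.character(ref),
                  alt = as.character(alt),
                  coding = coding,
                  stringsAsFactors = FALSE)
  if (any(m$ref == m$alt))
    stop("ref and alt alleles must differ")
  m$max_code <- ifelse(m$coding == "additive", 2L, 1L)
  class(m) <- c("cgx_manifest", "data.frame")
  m
}

#' Read a SNP manifest from YAML
#'
#' Expected layout: one top-level entry per SNP id, each with fields
#' \code{alleles: [ref, alt]} and \code{coding}.
#'
#' @param path path to a YAML file.
#' @return A \code{\link{snp_manifest}}.
#' @export
read_snp_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  if (length(y) == 0L) stop("empty manifest: ", path)
  snp_manifest(snp_id = names(y),
               ref = vapply(y, function(e) as.character(e$alleles[[1]]), ""),
               alt = vapply(y, function(e) as.character(e$alleles[[2]]), ""),
               coding = vapply(y, function(e) as.character(e$coding), ""))
}

#' Write a SNP manifest to YAML
#'
#' @param manifest a \code{\link{snp_manifest}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_snp_manifest <- function(manifest, path) {
  y <- lapply(seq_len(nrow(manifest)), function(i)
    list(alleles = c(manifest$ref[i], manifest$alt[i]),
         coding = manifest$coding[i]))
  names(y) <- manifest$snp_id
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The five-SNP manifest of the motivating metabolic syndrome study
#'
#' Alleles and codings as used in the case-control study of metabolic
#' syndrome and exercise-facility availability: additive coding for
#' rs1801282, rs822390 and rs182052; recessive for rs7799039 and rs12535708.
#'
#' @return A \code{\link{snp_manifest}} with five rows.
#' @export
paper_manifest <- function() {
  snp_manifest(
    snp_id = c("rs1801282", "rs7799039", "rs12535708", "rs822390", "rs182052"),
    ref    = c("C", "A", "C", "T", "A"),
    alt    = c("G", "G", "A", "G", "G"),
    coding = c("additive", "recessive", "recessive", "additive", "additive"))
}

#' Code a genotype under a genetic model
#'
#' Genotypes are unordered allele pairs written \code{"X/Y"} (\code{"G/C"}
#' equals \code{"C/G"}).  The missing genotype \code{"./."} codes to
#' \code{NA}.
#'
#' @param genotype character vector of \code{"X/Y"} genotype strings.
#' @param ref,alt single reference / alternative allele.
#' @param coding one of \code{"additive"}, \code{"dominant"},
#'   \code{"recessive"}.
#' @param snp_id,subject_id optional identifiers used in error messages.
#' @return Integer vector of codes: additive counts alt alleles (0, 1, 2);
#'   dominant is 1 for any alt carrier; recessive is 1 only for alt/alt.
#' @examples
#' code_genotype(c("C/G", "G/G", "C/C"), "C", "G", "additive")  # 1 2 0
#' code_genotype("A/G", "A", "G", "recessive")                  # 0
#' @export
code_genotype <- function(genotype, ref, alt, coding,
                          snp_id = "?", subject_id = NULL) {
  coding <- match.arg(coding, c("additive", "dominant", "recessive"))
  parts <- strsplit(as.character(genotype), "/", fixed = TRUE)
  bad_form <- lengths(parts) != 2L
  if (any(bad_form))
    stop("malformed genotype for SNP ", snp_id, ": ",
         paste(genotype[bad_form], collapse = ", "))
  a1 <- vapply(parts, `[`, "", 1L)
  a2 <- vapply(parts, `[`, "", 2L)
  missing <- a1 == "." & a2 == "."
  known <- c(ref, alt)
  bad <- !missing & (!(a1 %in% known) | !(a2 %in% known))
  if (any(bad)) {
    who <- if (is.null(subject_id)) which(bad)[1L] else subject_id[bad][1L]
    stop("unknown allele in genotype '", genotype[bad][1L], "' for SNP ",
         snp_id, " (subject ", who, "); declared alleles are ",
         ref, "/", alt)
  }
  n_alt <- (a1 == alt) + (a2 == alt)
  code <- switch(coding,
                 additive  = n_alt,
                 dominant  = as.integer(n_alt >= 1L),
                 recessive = as.integer(n_alt == 2L))
  code[missing] <- NA_integer_
  as.integer(code)
}
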