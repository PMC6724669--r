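# One-letter is the internal canonical form: "*" for stop, "=" for synonymous.
AA_1TO3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
             E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
             M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
             Y = "Tyr", V = "Val", `*` = "Ter")
AA_3TO1 <- stats::setNames(names(AA_1TO3), AA_1TO3)
# stop-codon spellings seen in the wild, mapped to "*"
STOP_SPELLINGS <- c("TER", "TERM", "STOP", "X", "*")

.aa_token_to_1 <- function(tok, allow_stop_x = FALSE) {
  # returns one-letter code or NA; tok already stripped
  if (nchar(tok) == 1L) {
    up <- toupper(tok)
    if (up == "*") return("*")
    if (up == "X") return(if (allow_stop_x) "*" else NA_character_)
    if (up %in% names(AA_1TO3) && up != "*") return(up)
    return(NA_character_)
  }
  up <- toupper(tok)
  if (up %in% STOP_SPELLINGS) return("*")
  t3 <- paste0(toupper(substr(tok, 1, 1)), tolower(substr(tok, 2, nchar(tok))))
  if (t3 %in% names(AA_3TO1)) return(unname(AA_3TO1[t3]))
  NA_character_
}

#' Parse a free-form protein-change notation
#'
#' Accepts the many HGVS-like protein dialects found in variant databases:
#' an optional `p.` prefix and parentheses, three- or one-letter amino-acid
#' codes, the stop-codon spellings `Ter`, `Term`, `Stop`, `X` and `*`, and
#' `=` for a synonymous change. `X` is treated as a stop only in the
#' alternate position. When the full grammar fails, a codon number is still
#' extracted if one is present, so partial information from dirty database
#' records is never discarded; nucleotide-level notations (`c.`, `g.`, ...)
#' fail outright. This function never raises on bad input.
#'
#' @param text Character vector of protein-change notations.
#' @return Data frame with columns `aa_ref`, `codon`, `aa_alt`, `status`
#'   (one of `"full"`, `"codon_only"`, `"failed"`) and `raw`.
#' @examples
#' parse_protein_change(c("p.Arg359Ter", "R359X", "p.Leu294=", "c.1075C>T"))
#' @export
parse_protein_change <- function(text) {
  text <- as.character(text)
  out <- data.frame(aa_ref = NA_character_, codon = NA_integer_,
                    aa_alt = NA_character_, status = "failed",
                    raw = text, stringsAsFactors = FALSE)
  for (i in seq_along(text)) {
    raw <- text[i]
    if (is.na(raw) || !nzchar(trimws(raw))) next
    s <- trimws(raw)
    # nucleotide-level HGVS is a different grammar entirely: fail, no salvage
    if (grepl("^[cgmnro]\\.", s, ignore.case = FALSE)) next
    s <- gsub("[()]", "", s)
    s <- sub("^p\\.", "", s, ignore.case = TRUE)
    m <- regmatches(s, regexec(
      "^([A-Za-z*]{1,3})([0-9]+)(=|\\*|[A-Za-z]{1,4})$", s))[[1]]
    ok <- FALSE
    if (length(m) == 4L) {
      aa_ref <- .aa_token_to_1(m[2], allow_stop_x = FALSE)
      codon <- suppressWarnings(as.integer(m[3]))
      aa_alt <- if (m[4] == "=") "=" else .aa_token_to_1(m[4], allow_stop_x = TRUE)
      if (!is.na(aa_ref) && !is.na(aa_alt) && !is.na(codon) && codon >= 1L) {
        out$aa_ref[i] <- aa_ref
        out$codon[i] <- codon
        out$aa_alt[i] <- aa_alt
        out$status[i] <- "full"
        ok <- TRUE
      }
    }
    if (!ok) {
      num <- regmatches(s, regexpr("[0-9]+", s))
      if (length(num) == 1L) {
        codon <- suppressWarnings(as.integer(num))
        if (!is.na(codon) && codon >= 1L) {
          out$codon[i] <- codon
          out$status[i] <- "codon_only"
        }
      }
    }
  }
  out
}

#' Render a parsed protein change canonically
#'
#' @param aa_ref,codon,aa_alt Components as produced by
#'   [parse_protein_change()] (one-letter codes, `*` stop, `=` synonymous).
#' @param style `"one"` for `R359*`, `"three"` for `Arg359Ter`.
#' @return Character vector of renderings (`NA` where components are missing).
#' @examples
#' render_protein_change("R", 359, "*", style = "three")
#' @export
render_protein_change <- function(aa_ref, codon, aa_alt, style = c("one", "three")) {
  style <- match.arg(style)
  n <- max(length(aa_ref), length(codon), length(aa_alt))
  aa_ref <- rep_len(aa_ref, n); codon <- rep_len(codon, n); aa_alt <- rep_len(aa_alt, n)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(aa_ref[i]) || is.na(codon[i]) || is.na(aa_alt[i])) next
    if (style == "one") {
      out[i] <- paste0(aa_ref[i], codon[i], aa_alt[i])
    } else {
      r3 <- unname(AA_1TO3[aa_ref[i]])
      a3 <- if (aa_alt[i] == "=") "=" else unname(AA_1TO3[aa_alt[i]])
      out[i] <- paste0(r3, codon[i], a3)
    }
  }
  out
}

.nomenclature_env <- new.env(parent = emptyenv())

.load_pathogenicity_map <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.nomenclature_env$path_map)) return(.nomenclature_env$path_map)
    path <- system.file("extdata", "pathogenicity_map.tsv", package = "varmedal")
  }
  map <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  stopifnot(all(c("raw_label", "standardized_code") %in% names(map)))
  .nomenclature_env$path_map <- map
  map
}

#' Standardize heterogeneous pathogenicity labels
#'
#' Maps the free-form pathogenicity vocabulary of curated variant databases
#' onto the five-tier codes `B`, `LB`, `VUS`, `LP`, `P`. The mapping ships
#' as an editable two-column data file; matching is case-insensitive and
#' separator-insensitive. Anything not covered maps to `"unmapped"` — dirty
#' labels are never silently promoted to pathogenic.
#'
#' @param text Character vector of raw labels.
#' @param map_file Optional path to a custom mapping table (tab-delimited,
#'   columns `raw_label`, `standardized_code`).
#' @return Character vector over `B`, `LB`, `VUS`, `LP`, `P`, `unmapped`.
#' @examples
#' standardize_pathogenicity(c("Likely pathogenic", "probably not pathogenic",
#'                             "conflicting interpretations"))
#' @export
standardize_pathogenicity <- function(text, map_file = NULL) {
  map <- .load_pathogenicity_map(map_file)
  norm <- function(x) {
    x <- tolower(trimws(as.character(x)))
    x <- gsub("[_-]+", " ", x)
    gsub("[[:space:]]+", " ", x)
  }
  lut <- stats::setNames(map$standardized_code, norm(map$raw_label))
  out <- unname(lut[norm(text)])
  out[is.na(out)] <- "unmapped"
  empty <- is.na(text) | !nzchar(trimws(text))
  out[empty] <- "unmapped"
  out
}
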