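# Fixed biological reference knowledge consulted by the classification rules:
# exon<->codon map of the canonical 393-residue p53, protein domain intervals,
# amino-acid polarity/charge groups, and the EAp53 score lookup.

#' Load a TP53 transcript exon/codon map
#'
#' Reads a tab-delimited exon table (columns \code{exon}, \code{first_codon},
#' \code{last_codon}; 1-based inclusive codon intervals) and validates that
#' the intervals are ordered, non-overlapping and jointly cover
#' \code{1..protein_length}.  The bundled default follows the canonical
#' 393-codon p53 transcript with coding exons 2--11; codons that span an
#' exon junction are assigned to the earlier exon so the map is a strict
#' partition.
#'
#' @param path path to the exon table; \code{NULL} loads the bundled default.
#' @param gene_symbol gene symbol carried in the model.
#' @param transcript_label free-text transcript label echoed in reports.
#' @return an object of class \code{transcript_model} with elements
#'   \code{gene_symbol}, \code{transcript_label}, \code{protein_length},
#'   \code{exons}.
#' @export
load_transcript_model <- function(path = NULL, gene_symbol = "TP53",
                                  transcript_label = "TP53 canonical (393 aa)") {
  if (is.null(path)) path <- extdata_path("tp53_exons.tsv")
  ex <- read_tsv_checked(path, c("exon", "first_codon", "last_codon"),
                         "transcript model")
  if (nrow(ex) == 0L) stop("parse error: transcript model has no exon rows",
                           call. = FALSE)
  for (col in c("exon", "first_codon", "last_codon")) {
    if (anyNA(ex[[col]]) || !is.numeric(ex[[col]])) {
      stop("parse error in transcript model: non-numeric or missing '", col,
           "' (row ", which(anyNA(ex[[col]]) | !is.finite(ex[[col]]))[1], ")",
           call. = FALSE)
    }
  }
  ex <- ex[order(ex$exon), , drop = FALSE]
  if (any(ex$first_codon > ex$last_codon)) {
    stop("validation error: exon with first_codon > last_codon", call. = FALSE)
  }
  if (ex$first_codon[1] != 1L) {
    stop("validation error: exon map does not start at codon 1", call. = FALSE)
  }
  if (nrow(ex) > 1L) {
    gaps <- ex$first_codon[-1] != ex$last_codon[-nrow(ex)] + 1L
    if (any(gaps)) {
      stop("validation error: exon map has a gap or overlap before exon ",
           ex$exon[-1][gaps][1], call. = FALSE)
    }
  }
  structure(
    list(gene_symbol = gene_symbol,
         transcript_label = transcript_label,
         protein_length = as.integer(max(ex$last_codon)),
         exons = data.frame(exon = as.integer(ex$exon),
                            first_codon = as.integer(ex$first_codon),
                            last_codon = as.integer(ex$last_codon))),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$gene_symbol, " [", x$transcript_label, "], ",
      x$protein_length, " aa, ", nrow(x$exons), " coding exons\n", sep = "")
  invisible(x)
}

#' Map a codon position to its exon
#'
#' @param model a \code{transcript_model}.
#' @param position integer vector of 1-based codon positions.
#' @return integer vector of exon numbers.
#' @export
codon_to_exon <- function(model, position) {
  stopifnot(inherits(model, "transcript_model"))
  position <- as.integer(position)
  if (anyNA(position) || any(position < 1L) ||
      any(position > model$protein_length)) {
    stop("position out of range 1..", model$protein_length, call. = FALSE)
  }
  idx <- findInterval(position, model$exons$first_codon)
  model$exons$exon[idx]
}

#' Load a p53 domain interval map
#'
#' Columns \code{name}, \code{start}, \code{end} (1-based inclusive residue
#' intervals).  The map must contain the DNA-binding domain ("DBD") and the
#' L2 and L3 loops, and the loops must lie inside the DBD.  The bundled
#' default places the DBD at residues 102--292 with L2 = 163--195 and
#' L3 = 236--251 (the convention of the disruptive-classification
#' literature); both loop intervals are configurable through this file.
#'
#' @param path path to the domain table; \code{NULL} loads the default.
#' @param protein_length upper bound for interval validation.
#' @return object of class \code{domain_map}.
#' @export
load_domain_map <- function(path = NULL, protein_length = 393L) {
  if (is.null(path)) path <- extdata_path("tp53_domains.tsv")
  dm <- read_tsv_checked(path, c("name", "start", "end"), "domain map")
  if (any(dm$start < 1L) || any(dm$end > protein_length) ||
      any(dm$start > dm$end)) {
    stop("validation error: domain interval outside 1..", protein_length,
         " or inverted", call. = FALSE)
  }
  for (d in c("DBD", "L2", "L3")) {
    if (!d %in% dm$name) stop("domain map must define '", d, "'", call. = FALSE)
  }
  dbd <- dm[dm$name == "DBD", ]
  for (loop in c("L2", "L3")) {
    lo <- dm[dm$name == loop, ]
    if (lo$start < dbd$start || lo$end > dbd$end) {
      stop("validation error: ", loop, " interval not contained in DBD",
           call. = FALSE)
    }
  }
  structure(list(domains = dm, protein_length = as.integer(protein_length)),
            class = "domain_map")
}

#' Domains containing a residue position
#'
#' @param map a \code{domain_map}.
#' @param position single 1-based residue position.
#' @return character vector of domain names containing the position
#'   (empty when the position lies outside every annotated domain).
#' @export
domain_of_residue <- function(map, position) {
  stopifnot(inherits(map, "domain_map"), length(position) == 1L)
  position <- as.integer(position)
  if (is.na(position) || position < 1L) {
    stop("position must be a positive integer", call. = FALSE)
  }
  d <- map$domains
  d$name[position >= d$start & position <= d$end]
}

# Vectorized membership test for one named domain (NA positions -> FALSE).
in_domain <- function(map, position, name) {
  d <- map$domains[map$domains$name == name, ]
  if (nrow(d) == 0L) return(rep(FALSE, length(position)))
  out <- rep(FALSE, length(position))
  ok <- !is.na(position)
  for (i in seq_len(nrow(d))) {
    out[ok] <- out[ok] | (position[ok] >= d$start[i] & position[ok] <= d$end[i])
  }
  out
}

#' Load the amino-acid polarity/charge grouping
#'
#' Columns \code{residue}, \code{group}; every one of the 20 standard
#' residues must appear exactly once.  The default grouping is the standard
#' biochemistry one: nonpolar \{G,A,V,L,I,P,F,M,W\}, polar-uncharged
#' \{S,T,C,Y,N,Q\}, positive \{K,R,H\}, negative \{D,E\}.
#'
#' @param path path to the table; \code{NULL} loads the default.
#' @return named character vector (class \code{residue_properties}) mapping
#'   residue to group label.
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("residue_groups.tsv")
  pt <- read_tsv_checked(path, c("residue", "group"), "property table")
  if (anyDuplicated(pt$residue)) {
    stop("validation error: duplicated residue in property table",
         call. = FALSE)
  }
  miss <- setdiff(AA_CODES, pt$residue)
  if (length(miss)) {
    stop("validation error: property table misses residue(s): ",
         paste(miss, collapse = ","), call. = FALSE)
  }
  structure(stats::setNames(as.character(pt$group), pt$residue),
            class = "residue_properties")
}

#' Test whether two residues share a polarity/charge group
#'
#' @param table a \code{residue_properties} mapping.
#' @param a,b one-letter residue codes (vectorized, recycled).
#' @return logical vector.
#' @export
same_property_group <- function(table, a, b) {
  stopifnot(inherits(table, "residue_properties"))
  bad <- setdiff(unique(c(a, b)), AA_CODES)
  if (length(bad)) {
    stop("nonstandard residue code: ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  unname(table[a] == table[b])
}

#' Load an EAp53 score lookup table
#'
#' Columns \code{ref}, \code{pos}, \code{alt}, \code{score}.  Scores must
#' lie in [0, 100]; the reference residue at a position must be unique.
#' The bundled table is synthetic (scores span the 75 decision threshold);
#' real evolutionary-action scores are an external input and are never
#' computed here.
#'
#' @param path path to the table; \code{NULL} loads the bundled synthetic
#'   default.
#' @return data.frame of class \code{ea_table}.
#' @export
load_ea_table <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("ea_scores_synthetic.tsv")
  ea <- read_tsv_checked(path, c("ref", "pos", "alt", "score"),
                         "EA score table")
  if (any(!is.finite(ea$score)) || any(ea$score < 0) || any(ea$score > 100)) {
    stop("validation error: EA score outside [0, 100]", call. = FALSE)
  }
  refs <- unique(ea[, c("ref", "pos")])
  if (anyDuplicated(refs$pos)) {
    stop("validation error: conflicting reference residues at position ",
         refs$pos[duplicated(refs$pos)][1], call. = FALSE)
  }
  if (anyDuplicated(paste(ea$ref, ea$pos, ea$alt))) {
    stop("validation error: duplicated (ref, pos, alt) entry", call. = FALSE)
  }
  class(ea) <- c("ea_table", "data.frame")
  ea
}

#' Look up an EAp53 score
#'
#' Absence is a value (\code{NA}), never silently zero.
#'
#' @param table an \code{ea_table}.
#' @param ref,position,alt substitution key (vectorized, recycled).
#' @return numeric vector; \code{NA} where the triple is absent.
#' @export
lookup_ea_score <- function(table, ref, position, alt) {
  stopifnot(inherits(table, "ea_table"))
  key <- paste(ref, position, alt, sep = "|")
  tab_key <- paste(table$ref, table$pos, table$alt, sep = "|")
  table$score[match(key, tab_key)]
}

#' Reference protein sequence used by the synthetic-cohort generator
#'
#' The bundled sequence is \emph{synthetic}: NSCLC hotspot residues
#' (e.g. R110, R158, R175, Y220, Y236, G245, R248, R249, R273, R280, R282,
#' E285, E298) are pinned to their true p53 amino acids so hotspot variant
#' strings are biologically coherent, while the remaining positions are
#' pseudorandom placeholders.  It exists so that simulated variants carry a
#' consistent reference residue at every position; it is not the real p53
#' sequence.
#'
#' @param path path to a plain-text sequence file; \code{NULL} loads the
#'   bundled synthetic default.
#' @return single character string of one-letter residues.
#' @export
load_protein_sequence <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("tp53_protein_synthetic.txt")
  s <- paste(gsub("[[:space:]]", "", readLines(path)), collapse = "")
  if (nchar(s) == 0L) stop("empty protein sequence file", call. = FALSE)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), AA_CODES)
  if (length(bad)) {
    stop("invalid residue code(s) in sequence: ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  s
}

#' Load every bundled reference object at once
#'
#' @param transcript,domains,properties,ea_scores,sequence optional paths
#'   overriding the bundled defaults.
#' @return list with elements \code{model}, \code{domains},
#'   \code{properties}, \code{ea}, \code{sequence}.
#' @export
load_reference_set <- function(transcript = NULL, domains = NULL,
                               properties = NULL, ea_scores = NULL,
                               sequence = NULL) {
  model <- load_transcript_model(transcript)
  list(model = model,
       domains = load_domain_map(domains, model$protein_length),
       properties = load_property_table(properties),
       ea = load_ea_table(ea_scores),
       sequence = load_protein_sequence(sequence))
}
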