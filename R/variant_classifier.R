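# Parse TP53 protein-change strings and derive the per-variant functional
# annotation: effect class, truncating flag, exon, domain membership,
# disruptive/nondisruptive call, and EAp53 risk class.

EFFECT_LEVELS <- c("missense", "nonsense", "frameshift", "splice",
                   "inframe_indel", "synonymous", "other")
TRUNCATING_EFFECTS <- c("nonsense", "frameshift", "splice")

# MAF Variant_Classification vocabulary -> internal effect class.
CLASSIFICATION_MAP <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Del   = "frameshift",
  Frame_Shift_Ins   = "frameshift",
  Splice_Site       = "splice",
  Splice_Region     = "splice",
  In_Frame_Del      = "inframe_indel",
  In_Frame_Ins      = "inframe_indel",
  Silent            = "synonymous",
  Synonymous        = "synonymous")

parse_one_hgvs <- function(raw, classification = NA_character_) {
  out <- list(raw_hgvs = raw, ref_residue = NA_character_,
              position = NA_integer_, alt_residue = NA_character_,
              effect = NA_character_)
  cls <- if (!is.na(classification) && classification %in% names(CLASSIFICATION_MAP))
    CLASSIFICATION_MAP[[classification]] else NA_character_
  s <- trimws(if (is.na(raw)) "" else raw)
  s <- sub("^p\\.", "", s)
  # Splice variants carry no protein-level fields (MAF writes e.g. X187_splice)
  if (grepl("splice", s, ignore.case = TRUE) ||
      (identical(cls, "splice") && !nzchar(s))) {
    out$effect <- "splice"
    return(out)
  }
  if (!nzchar(s)) {
    if (!is.na(cls)) { out$effect <- cls; return(out) }
    stop("cannot parse protein change: '", raw, "'", call. = FALSE)
  }
  # Normalize the stop symbol: X / Ter / * are one internal symbol.
  s <- sub("Ter$", "*", s)
  s <- sub("^([A-Z])([0-9]+)X$", "\\1\\2*", s)

  m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z*]?)fs[*A-Za-z0-9]*$", s))[[1]]
  if (length(m)) {
    check_residue(m[2], raw)
    out$ref_residue <- m[2]
    out$position <- as.integer(m[3])
    out$effect <- "frameshift"
    return(out)
  }
  m <- regmatches(s, regexec("^([A-Z])([0-9]+)\\*$", s))[[1]]
  if (length(m)) {
    check_residue(m[2], raw)
    out$ref_residue <- m[2]
    out$position <- as.integer(m[3])
    out$alt_residue <- STOP_SYMBOL
    out$effect <- "nonsense"
    return(out)
  }
  m <- regmatches(s, regexec("^([A-Z])([0-9]+)=$", s))[[1]]
  if (length(m)) {
    check_residue(m[2], raw)
    out$ref_residue <- m[2]
    out$position <- as.integer(m[3])
    out$alt_residue <- m[2]
    out$effect <- "synonymous"
    return(out)
  }
  m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z])$", s))[[1]]
  if (length(m)) {
    check_residue(m[2], raw); check_residue(m[4], raw)
    out$ref_residue <- m[2]
    out$position <- as.integer(m[3])
    out$alt_residue <- m[4]
    out$effect <- if (m[2] == m[4]) "synonymous" else "missense"
    return(out)
  }
  if (grepl("del|ins|dup", s) && !grepl("fs", s)) {
    m <- regmatches(s, regexec("^([A-Z])([0-9]+)", s))[[1]]
    if (length(m) && m[2] %in% AA_CODES) {
      out$ref_residue <- m[2]
      out$position <- as.integer(m[3])
    }
    out$effect <- "inframe_indel"
    return(out)
  }
  if (!is.na(cls)) {
    # String shape unknown but the MAF effect column is explicit.
    out$effect <- cls
    return(out)
  }
  stop("cannot parse protein change: '", raw, "'", call. = FALSE)
}

check_residue <- function(code, raw) {
  if (!code %in% AA_CODES) {
    stop("cannot parse protein change: '", raw,
         "' (nonstandard residue '", code, "')", call. = FALSE)
  }
}

#' Parse HGVS protein-change strings
#'
#' Accepts the dialects found in MAF-style tables: with or without the
#' \code{p.} prefix; stop written \code{X}, \code{*} or \code{Ter};
#' frameshifts with any \code{fs} suffix; splice records flagged by a
#' \code{splice} token or by the \code{Variant_Classification} column.
#' Unparseable strings raise an error carrying the raw text; they are never
#' silently skipped.
#'
#' @param x character vector of protein-change strings.
#' @param classification optional parallel character vector of MAF
#'   \code{Variant_Classification} values, consulted when the string itself
#'   is absent or shapeless (splice records).
#' @return data.frame with columns \code{raw_hgvs}, \code{ref_residue},
#'   \code{position}, \code{alt_residue}, \code{effect}.
#' @examples
#' parse_hgvs_p(c("R282W", "E298X", "p.E298*", "R213fs"))
#' @export
parse_hgvs_p <- function(x, classification = NULL) {
  if (length(x) == 0L) stop("no protein change supplied", call. = FALSE)
  if (is.null(classification)) classification <- rep(NA_character_, length(x))
  classification <- rep_len(as.character(classification), length(x))
  rows <- lapply(seq_along(x), function(i) {
    parse_one_hgvs(x[i], classification[i])
  })
  data.frame(
    raw_hgvs = vapply(rows, `[[`, character(1), "raw_hgvs"),
    ref_residue = vapply(rows, `[[`, character(1), "ref_residue"),
    position = vapply(rows, `[[`, integer(1), "position"),
    alt_residue = vapply(rows, `[[`, character(1), "alt_residue"),
    effect = vapply(rows, `[[`, character(1), "effect"),
    stringsAsFactors = FALSE)
}

#' Format a parsed variant back to its normalized string
#'
#' Inverse of [parse_hgvs_p()] on the normalized form (stop printed
#' \code{*}, frameshifts as \code{<ref><pos>fs}, splice as \code{splice}).
#'
#' @param parsed data.frame as returned by [parse_hgvs_p()].
#' @return character vector.
#' @export
format_hgvs_p <- function(parsed) {
  vapply(seq_len(nrow(parsed)), function(i) {
    p <- parsed[i, ]
    switch(p$effect,
           missense   = ,
           synonymous = ,
           nonsense   = paste0(p$ref_residue, p$position, p$alt_residue),
           frameshift = paste0(p$ref_residue, p$position, "fs"),
           splice     = "splice",
           p$raw_hgvs)
  }, character(1))
}

#' EAp53 risk class from a score
#'
#' The threshold rule applies to missense variants only: score > 75 is
#' high-risk, score <= 75 is low-risk; non-missense variants and missense
#' variants without a score are \code{not_applicable}.
#'
#' @param score numeric vector in [0, 100] (NA allowed).
#' @param effect character vector of effect classes.
#' @return character vector in \code{\{high_risk, low_risk, not_applicable\}}.
#' @export
eap53_class <- function(score, effect) {
  n <- max(length(score), length(effect))
  score <- rep_len(score, n); effect <- rep_len(effect, n)
  bad <- !is.na(score) & (score < 0 | score > 100)
  if (any(bad)) {
    stop("EA score outside [0, 100]: ", score[bad][1], call. = FALSE)
  }
  out <- rep("not_applicable", n)
  app <- effect == "missense" & !is.na(score)
  out[app & score > 75] <- "high_risk"
  out[app & score <= 75] <- "low_risk"
  out
}

#' Annotate parsed variants with the full functional classification
#'
#' Applies the disruptive/nondisruptive rule: truncating variants
#' (nonsense, frameshift, splice) are disruptive; a missense substitution
#' is disruptive iff its position lies in the L2 or L3 loop of the
#' DNA-binding domain \emph{and} the reference and alternate residues
#' belong to different polarity/charge groups.  All other variants are
#' nondisruptive.  EAp53 risk classes are attached to missense variants
#' with a score (a supplied \code{ea_score} column wins over the lookup
#' table).
#'
#' @param variants a data.frame from [parse_hgvs_p()] (extra columns such
#'   as \code{patient_id} are carried through) or a character vector of
#'   protein changes.
#' @param model a \code{transcript_model}.
#' @param domains a \code{domain_map}.
#' @param properties a \code{residue_properties} table.
#' @param ea optional \code{ea_table} for score lookup.
#' @param ea_score optional numeric vector of per-variant scores overriding
#'   the lookup.
#' @return the input data.frame with columns \code{is_truncating},
#'   \code{exon}, \code{in_dbd}, \code{in_l2_l3}, \code{is_disruptive},
#'   \code{ea_score}, \code{eap53_class} appended.
#' @export
annotate_variants <- function(variants, model, domains, properties,
                              ea = NULL, ea_score = NULL) {
  if (is.character(variants)) variants <- parse_hgvs_p(variants)
  stopifnot(is.data.frame(variants),
            all(c("ref_residue", "position", "alt_residue", "effect")
                %in% names(variants)))
  v <- variants
  n <- nrow(v)
  pos <- v$position
  over <- !is.na(pos) & v$effect == "missense" & pos > model$protein_length
  if (any(over)) {
    stop("annotation error: position ", pos[over][1],
         " exceeds protein length ", model$protein_length, call. = FALSE)
  }
  v$is_truncating <- v$effect %in% TRUNCATING_EFFECTS

  v$exon <- rep(NA_integer_, n)
  known <- !is.na(pos) & pos >= 1L & pos <= model$protein_length
  if (any(known)) v$exon[known] <- codon_to_exon(model, pos[known])

  v$in_dbd <- in_domain(domains, pos, "DBD")
  v$in_l2_l3 <- in_domain(domains, pos, "L2") | in_domain(domains, pos, "L3")

  diff_group <- rep(FALSE, n)
  mis <- v$effect == "missense" & !is.na(v$ref_residue) & !is.na(v$alt_residue)
  if (any(mis)) {
    diff_group[mis] <- !same_property_group(properties, v$ref_residue[mis],
                                            v$alt_residue[mis])
  }
  v$is_disruptive <- v$is_truncating | (mis & v$in_l2_l3 & diff_group)

  score <- if (!is.null(ea_score)) rep_len(as.numeric(ea_score), n)
           else rep(NA_real_, n)
  if (!is.null(ea)) {
    fill <- mis & is.na(score)
    if (any(fill)) {
      score[fill] <- lookup_ea_score(ea, v$ref_residue[fill], pos[fill],
                                     v$alt_residue[fill])
    }
  }
  bad <- !is.na(score) & (score < 0 | score > 100)
  if (any(bad)) stop("EA score outside [0, 100]: ", score[bad][1],
                     call. = FALSE)
  score[v$effect != "missense"] <- NA_real_
  v$ea_score <- score
  v$eap53_class <- eap53_class(score, v$effect)
  v
}
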