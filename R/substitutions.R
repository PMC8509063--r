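#' Parse and format substitution genotypes
#'
#' A single amino-acid substitution is written in the conventional
#' `<ref><position><alt>` form (e.g. `"M7W"`); a variant genotype is a
#' comma-separated, position-sorted set of such substitutions, with at
#' most one substitution per position. The wild-type genotype (no
#' substitutions) is written `"WT"`.
#'
#' @param genotype Genotype string such as `"M7W,I12S"` or `"WT"`.
#' @return `parse_genotype()`: data frame with columns `position`
#'   (integer), `ref`, `alt` and `sub` (the canonical text form), ordered
#'   by position. Zero rows for the wild type.
#' @examples
#' parse_genotype("I12S,M7W")      # reordered by position
#' format_genotype(data.frame(position = c(12, 7), ref = c("I", "M"),
#'                            alt = c("S", "W")))
#' @export
parse_genotype <- function(genotype) {
  stopifnot(is.character(genotype), length(genotype) == 1L)
  genotype <- gsub(" ", "", genotype)
  if (genotype %in% c("", "WT"))
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), sub = character()))
  subs <- strsplit(genotype, ",", fixed = TRUE)[[1]]
  m <- regmatches(subs, regexec("^([A-Z])([0-9]+)([A-Z*])$", subs))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("malformed substitution(s): ", paste(subs[bad], collapse = ", "))
  ref <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  alt <- vapply(m, `[`, "", 4L)
  if (any(ref == alt))
    stop("substitution with identical reference and alternate residue: ",
         paste(subs[ref == alt], collapse = ", "))
  if (anyDuplicated(pos))
    stop("genotype carries more than one substitution at position(s): ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "))
  o <- order(pos)
  data.frame(position = pos[o], ref = ref[o], alt = alt[o],
             sub = paste0(ref, pos, alt)[o])
}

#' @rdname parse_genotype
#' @param subs Data frame with columns `position`, `ref`, `alt`, or a
#'   character vector of `<ref><pos><alt>` substitution strings.
#' @return `format_genotype()`: the canonical genotype string.
#' @export
format_genotype <- function(subs) {
  if (is.character(subs)) {
    if (length(subs) == 0L) return("WT")
    return(format_genotype(parse_genotype(paste(subs, collapse = ","))))
  }
  if (nrow(subs) == 0L) return("WT")
  o <- order(subs$position)
  paste0(subs$ref[o], subs$position[o], subs$alt[o], collapse = ",")
}

# positions touched by a genotype string (integer(0) for "WT")
genotype_positions <- function(genotype) {
  if (genotype %in% c("", "WT")) return(integer())
  as.integer(regmatches(genotype, gregexpr("[0-9]+", genotype))[[1]])
}

# number of substitutions in a genotype string, vectorised
genotype_size <- function(genotype) {
  n <- lengths(regmatches(genotype, gregexpr(",", genotype, fixed = TRUE))) + 1L
  n[genotype %in% c("", "WT")] <- 0L
  n
}

# split genotype strings into substitution string sets, vectorised
genotype_subs <- function(genotype) {
  out <- strsplit(genotype, ",", fixed = TRUE)
  out[genotype %in% c("", "WT")] <- list(character())
  out
}
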