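#' @keywords internal
"_PACKAGE"

VARIANT_KINDS <- c("SNP", "small_indel", "IS_insertion", "large_deletion")
SYN_LEVELS <- c("synonymous", "nonsynonymous", "noncoding")
CALLSET_ROLES <- c("donor", "recipient", "recombinant", "population")

#' Construct a variant table
#'
#' A variant table is the universal currency of the pipeline: one row per
#' variant site relative to a shared reference chromosome. Site identity is
#' the tuple `(chrom, pos, kind, alt)`; positions are 1-based and inclusive.
#' Large deletions are stored as a single row whose `alt` is the deleted span
#' length in bp.
#'
#' @param chrom reference sequence id (recycled if length 1).
#' @param pos 1-based position on the reference.
#' @param kind one of `"SNP"`, `"small_indel"`, `"IS_insertion"`,
#'   `"large_deletion"`.
#' @param alt allele descriptor: base(s) for SNP/indel, element name for IS
#'   insertions, span length (bp, as character or numeric) for deletions.
#' @param gene optional gene name (`NA` when intergenic/unknown).
#' @param syn optional coding annotation: `"synonymous"`, `"nonsynonymous"`,
#'   or `"noncoding"`.
#' @param freq optional allele frequency in `[0, 1]` (population samples).
#' @return a `data.frame` with columns `chrom, pos, kind, alt, gene, syn,
#'   freq`, one row per site.
#' @examples
#' variant_table(pos = c(100, 250), kind = c("SNP", "large_deletion"),
#'               alt = c("A", "500"))
#' @export
variant_table <- function(chrom = "chromosome", pos = integer(), kind = character(),
                          alt = character(), gene = NA_character_,
                          syn = NA_character_, freq = NA_real_) {
  n <- max(length(pos), length(kind), length(alt))
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(), kind = character(),
                      alt = character(), gene = character(), syn = character(),
                      freq = numeric(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(rep_len(pos, n)),
    kind = rep_len(as.character(kind), n),
    alt = rep_len(as.character(alt), n),
    gene = rep_len(as.character(gene), n),
    syn = rep_len(as.character(syn), n),
    freq = rep_len(as.numeric(freq), n),
    stringsAsFactors = FALSE
  )
  validate_variant_table(df)
  df
}

validate_variant_table <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("chrom", "pos", "kind", "alt")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("variant table is missing columns: ", paste(missing, collapse = ", "))
  if (any(df$pos < 1L, na.rm = TRUE))
    stop("variant positions must be >= 1 (1-based coordinates)")
  bad <- setdiff(unique(df$kind), VARIANT_KINDS)
  if (length(bad) > 0L)
    stop("unknown variant kind(s): ", paste(bad, collapse = ", "))
  del <- df$kind == "large_deletion"
  if (any(del)) {
    span <- suppressWarnings(as.numeric(df$alt[del]))
    if (any(is.na(span)) || any(span < 1))
      stop("large_deletion rows must carry a span >= 1 in `alt`")
  }
  badsyn <- setdiff(stats::na.omit(unique(df$syn)), SYN_LEVELS)
  if (length(badsyn) > 0L)
    stop("unknown syn annotation(s): ", paste(badsyn, collapse = ", "))
  if (!is.null(df$freq) && any(!is.na(df$freq) & (df$freq < 0 | df$freq > 1)))
    stop("frequencies must lie in [0, 1]")
  invisible(df)
}

#' Site identity keys
#'
#' Identity of a site is the tuple `(chrom, pos, kind, alt)`; two records with
#' equal keys are the same site. Keys are plain strings so they can be used
#' with R's set operations.
#'
#' @param df a variant table.
#' @return character vector of keys, one per row.
#' @export
site_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  paste(df$chrom, df$pos, df$kind, df$alt, sep = "\r")
}

#' Construct a genome call set
#'
#' Binds a variant table to a sample id and an experimental role. Population
#' call sets must carry an allele frequency for every site; clone call sets
#' (donor/recipient/recombinant) ignore the `freq` column.
#'
#' @param sample_id sample name.
#' @param role one of `"donor"`, `"recipient"`, `"recombinant"`,
#'   `"population"`.
#' @param variants a variant table (see [variant_table()]).
#' @return an object of class `call_set`.
#' @export
call_set <- function(sample_id, role, variants) {
  role <- match.arg(role, CALLSET_ROLES)
  validate_variant_table(variants)
  keys <- site_key(variants)
  if (anyDuplicated(keys))
    stop("duplicate site identities in call set '", sample_id, "'")
  if (role == "population" && nrow(variants) > 0L && anyNA(variants$freq))
    stop("population call set '", sample_id, "' has sites without frequencies")
  structure(list(sample_id = sample_id, role = role, variants = variants),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf("<call_set> %s (%s): %d sites\n",
              x$sample_id, x$role, nrow(x$variants)))
  invisible(x)
}

#' @export
format.call_set <- function(x, ...) {
  sprintf("<call_set> %s (%s): %d sites", x$sample_id, x$role, nrow(x$variants))
}

# Accept either a call_set or a bare variant table wherever a set of sites is
# needed.
as_variants <- function(x) {
  if (inherits(x, "call_set")) x$variants
  else { validate_variant_table(x); x }
}

#' Deletion spans of a call set
#'
#' Large deletions are stored as single sites plus a span; this extracts the
#' covered intervals so that the provenance module can answer "is position p
#' inside a deletion called in this genome".
#'
#' @param x a `call_set` or variant table.
#' @return data.frame with columns `chrom, start, end` (1-based inclusive).
#' @export
deletion_spans <- function(x) {
  v <- as_variants(x)
  del <- v[v$kind == "large_deletion", , drop = FALSE]
  if (nrow(del) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  span <- as.numeric(del$alt)
  data.frame(chrom = del$chrom, start = del$pos,
             end = as.integer(del$pos + span - 1), stringsAsFactors = FALSE)
}

#' Test positions for membership in called deletions
#'
#' @param chrom,pos vectors of equal length (chrom recycled).
#' @param x a `call_set` or variant table whose deletions are queried.
#' @return logical vector: is each position inside a large deletion of `x`?
#' @export
in_deletion <- function(chrom, pos, x) {
  spans <- deletion_spans(x)
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  if (nrow(spans) == 0L) return(rep(FALSE, n))
  vapply(seq_len(n), function(i) {
    any(spans$chrom == chrom[i] & spans$start <= pos[i] & pos[i] <= spans$end)
  }, logical(1))
}

# Stable deterministic site ordering: (chrom, pos, kind, alt).
order_sites <- function(df) {
  df[order(df$chrom, df$pos, match(df$kind, VARIANT_KINDS), df$alt,
           method = "radix"), , drop = FALSE]
}
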