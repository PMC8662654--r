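#' Read mutation calls from a TSV or VCF file
#'
#' Reads one table of per-timepoint polymorphism calls, as produced downstream
#' of a breseq-style caller, into a validated data frame of mutation calls.
#' The native TSV dialect has one row per (mutation, timepoint) observation
#' with the columns `population`, `day`, `position`, `ref`, `alt`, `kind`,
#' `effect`, `locus`, `frequency`, `fwd_reads`, `rev_reads`, `depth`.
#' Coordinates are 1-based inclusive; indels are anchored at the first changed
#' base.
#'
#' For `dialect = "vcf"` a single-sample VCF is read (via the vcfR package):
#' the allele frequency is taken from the `AF` INFO tag and strand-resolved
#' read support from a `DP4`-style tag (ref-fwd, ref-rev, alt-fwd, alt-rev).
#' `population` and `day` are not encoded in VCF and must be supplied.
#'
#' @param path Path to the input file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param population,day Population label and sampling day, required for the
#'   VCF dialect (ignored for TSV, where they are columns).
#' @return A data frame of validated mutation calls in the native dialect.
#'   Malformed rows raise an error naming the offending row numbers.
#' @export
read_calls <- function(path, dialect = c("tsv", "vcf"),
                       population = NULL, day = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort("file not found: ", path)
  if (dialect == "tsv") {
    # read everything as character first: allele columns like "T" must not
    # be mistaken for logicals
    calls <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    missing_cols <- setdiff(call_columns(), names(calls))
    if (length(missing_cols) > 0)
      abort("missing required column(s): ", paste(missing_cols, collapse = ", "))
    calls <- calls[call_columns()]
    for (col in c("population", "ref", "alt", "kind", "effect", "locus"))
      calls[[col]] <- as.character(calls[[col]])
    for (col in c("day", "position", "fwd_reads", "rev_reads", "depth"))
      calls[[col]] <- as.integer(calls[[col]])
    calls$frequency <- as.numeric(calls$frequency)
  } else {
    calls <- read_calls_vcf(path, population, day)
  }
  validate_calls(calls)
}

call_columns <- function() {
  c("population", "day", "position", "ref", "alt", "kind", "effect",
    "locus", "frequency", "fwd_reads", "rev_reads", "depth")
}

validate_calls <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  bad <- which(is.na(calls$frequency) | calls$frequency < 0 | calls$frequency > 1)
  if (length(bad) > 0)
    abort("frequency outside [0,1] in row(s): ", paste(bad, collapse = ", "))
  bad <- which(calls$position < 1 | calls$day < 0)
  if (length(bad) > 0)
    abort("invalid position/day in row(s): ", paste(bad, collapse = ", "))
  bad <- which(calls$fwd_reads + calls$rev_reads > calls$depth)
  if (length(bad) > 0)
    abort("strand reads exceed depth in row(s): ", paste(bad, collapse = ", "))
  rownames(calls) <- NULL
  calls
}

read_calls_vcf <- function(path, population, day) {
  if (is.null(population) || is.null(day))
    abort("population and day must be supplied for the VCF dialect")
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("the vcfR package is required to read VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.null(nrow(fix))) t(fix) else fix
  af <- as.numeric(vcfR::extract.info(v, "AF"))
  dp4 <- vcfR::extract.info(v, "DP4")
  dp4 <- do.call(rbind, lapply(strsplit(dp4, ","), as.integer))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  kind <- ifelse(nchar(ref) == nchar(alt), "SNP",
                 ifelse(nchar(ref) < nchar(alt), "insertion", "deletion"))
  data.frame(population = population, day = day,
             position = as.integer(fix[, "POS"]), ref = ref, alt = alt,
             kind = kind, effect = "intergenic", locus = NA_character_,
             frequency = af, fwd_reads = dp4[, 3], rev_reads = dp4[, 4],
             depth = rowSums(dp4), stringsAsFactors = FALSE)
}

#' Remove variants already present in the ancestral strain
#'
#' Calls whose (position, alt) pair appears in the ancestral variant set are
#' dropped before any downstream analysis, so only mutations that arose during
#' the experiment remain.
#'
#' @param calls Mutation-call data frame (see [read_calls()]).
#' @param ancestor Data frame with columns `position` and `alt`.
#' @return The calls not matching any ancestral variant.
#' @export
subtract_ancestor <- function(calls, ancestor) {
  if (nrow(calls) == 0 || is.null(ancestor) || nrow(ancestor) == 0) return(calls)
  key <- paste(calls$position, calls$alt)
  anc <- unique(paste(ancestor$position, ancestor$alt))
  out <- calls[!(key %in% anc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter calls on strand-resolved read support
#'
#' Requires a mutation call to be supported by at least `min_per_strand` reads
#' on each strand. With `scope = "call"` the rule is applied to every
#' observation independently; with `scope = "mutation"` a mutation that passes
#' at one or more sampled timepoints keeps all of its observations, so that a
#' real trajectory is not zeroed at timepoints where coverage happened to be
#' one-sided.
#'
#' @param calls Mutation-call data frame.
#' @param min_per_strand Minimum reads required on each strand (default 3).
#' @param scope `"call"` (default) or `"mutation"`.
#' @return The retained calls.
#' @export
filter_strand_support <- function(calls, min_per_strand = 3,
                                  scope = c("call", "mutation")) {
  scope <- match.arg(scope)
  if (nrow(calls) == 0) return(calls)
  pass <- calls$fwd_reads >= min_per_strand & calls$rev_reads >= min_per_strand
  keep <- if (scope == "call") pass else {
    key <- mutation_key(calls, with_population = TRUE)
    key %in% unique(key[pass])
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

mutation_key <- function(calls, with_population = FALSE) {
  key <- sprintf("%d:%s>%s", calls$position, calls$ref, calls$alt)
  if (with_population) key <- paste(calls$population, key)
  key
}

#' Exclude calls in locally dense polymorphism windows
#'
#' Clusters of co-called polymorphisms within a short window are a signature
#' of read misalignment in repetitive sequence. Within each population and
#' sampling day, a call is dropped when more than `max_neighbors` other calls
#' lie within `window` bp on either side of its position. The rule is
#' symmetric and order-independent: neighbour counts are taken on the input
#' set, not updated as calls are removed.
#'
#' @param calls Mutation-call data frame.
#' @param window Window half-width in bp (default 15).
#' @param max_neighbors Maximum tolerated co-called neighbours (default 2).
#' @return The retained calls.
#' @export
filter_dense_windows <- function(calls, window = 15, max_neighbors = 2) {
  if (nrow(calls) == 0) return(calls)
  grp <- paste(calls$population, calls$day)
  keep <- rep(TRUE, nrow(calls))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    pos <- calls$position[idx]
    n_neighbors <- vapply(seq_along(pos), function(i) {
      sum(abs(pos - pos[i]) <= window) - 1L
    }, integer(1))
    keep[idx[n_neighbors > max_neighbors]] <- FALSE
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask calls falling in known misalignment regions
#'
#' Drops calls whose position lies inside any interval of a repeat mask.
#' Intervals are 1-based inclusive on both ends and are normalised (sorted,
#' overlaps merged) before use.
#'
#' @param calls Mutation-call data frame.
#' @param mask Data frame with columns `start` and `end` (1-based inclusive).
#' @return The retained calls.
#' @export
filter_repeat_mask <- function(calls, mask) {
  if (nrow(calls) == 0 || is.null(mask) || nrow(mask) == 0) return(calls)
  mask <- normalize_mask(mask)
  inside <- vapply(calls$position, function(p) {
    any(p >= mask$start & p <= mask$end)
  }, logical(1))
  out <- calls[!inside, , drop = FALSE]
  rownames(out) <- NULL
  out
}

normalize_mask <- function(mask) {
  if (any(mask$start > mask$end)) abort("mask interval with start > end")
  mask <- mask[order(mask$start, mask$end), , drop = FALSE]
  start <- integer(0); end <- integer(0)
  for (i in seq_len(nrow(mask))) {
    if (length(start) > 0 && mask$start[i] <= end[length(end)] + 1) {
      end[length(end)] <- max(end[length(end)], mask$end[i])
    } else {
      start <- c(start, mask$start[i]); end <- c(end, mask$end[i])
    }
  }
  data.frame(start = start, end = end)
}

#' Read an ancestral variant set or repeat mask from disk
#'
#' `read_ancestor_set()` expects a TSV with columns `position` and `alt`.
#' `read_repeat_mask()` accepts either a TSV with 1-based inclusive `start`
#' and `end` columns or a 3-column BED file (0-based half-open, converted on
#' read; files ending in `.bed` are treated as BED).
#'
#' @param path Path to the file.
#' @return A data frame suitable for [subtract_ancestor()] or
#'   [filter_repeat_mask()].
#' @export
read_ancestor_set <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("position", "alt") %in% names(x)))
    abort("ancestor set needs 'position' and 'alt' columns")
  unique(x[c("position", "alt")])
}

#' @rdname read_ancestor_set
#' @export
read_repeat_mask <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    mask <- data.frame(start = x[[2]] + 1L, end = x[[3]])
  } else {
    x <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("start", "end") %in% names(x)))
      abort("repeat mask needs 'start' and 'end' columns")
    mask <- x[c("start", "end")]
  }
  normalize_mask(mask)
}

#' Consolidate calls into a per-population trajectory table
#'
#' Builds the mutation-by-day frequency matrix that is the central object of
#' the pipeline. Mutation identity is the (position, ref, alt) triple; the
#' same position with a different alternate allele is a distinct mutation.
#' Cells where a mutation was not called at a sampled day are 0 ("sampled but
#' below detection"), not missing.
#'
#' @param calls Mutation-call data frame from a single population.
#' @param days Sampled days (strictly increasing). Defaults to the sorted
#'   unique days present in `calls`; pass explicitly when some sampled days
#'   yielded no calls.
#' @return An object of class `trajectory_table`: a list with elements
#'   `population`, `days`, `mutations` (data frame: `id`, `position`, `ref`,
#'   `alt`, `locus`, `effect`, `kind`) and `freq` (mutations x days matrix).
#' @export
build_trajectories <- function(calls, days = NULL) {
  if (nrow(calls) == 0) abort("no calls to consolidate")
  pop <- unique(calls$population)
  if (length(pop) != 1) abort("calls must come from a single population")
  if (is.null(days)) days <- sort(unique(calls$day))
  if (is.unsorted(days, strictly = TRUE)) abort("days must be strictly increasing")
  if (!all(calls$day %in% days)) abort("calls contain days outside 'days'")

  key <- mutation_key(calls)
  if (anyDuplicated(paste(key, calls$day)) > 0)
    abort("duplicate (mutation, day) pair in calls")

  first <- calls[!duplicated(key), , drop = FALSE]
  ord <- order(first$position, first$ref, first$alt)
  first <- first[ord, , drop = FALSE]
  ids <- mutation_key(first)
  mutations <- data.frame(id = ids, position = first$position, ref = first$ref,
                          alt = first$alt, locus = first$locus,
                          effect = first$effect, kind = first$kind,
                          stringsAsFactors = FALSE)

  freq <- matrix(0, nrow = length(ids), ncol = length(days),
                 dimnames = list(ids, paste0("day", days)))
  freq[cbind(match(key, ids), match(calls$day, days))] <- calls$frequency

  structure(list(population = pop, days = days, mutations = mutations,
                 freq = freq),
            class = "trajectory_table")
}

#' @export
print.trajectory_table <- function(x, ...) {
  cat(sprintf("<trajectory_table> population %s: %d mutations x %d days (%s)\n",
              x$population, nrow(x$freq), length(x$days),
              paste(x$days, collapse = ", ")))
  invisible(x)
}

#' Classify a base substitution
#'
#' Single-base A<->G and C<->T changes are transitions, other single-base
#' changes are transversions, and any length change is an indel. Ambiguous
#' base codes are rejected.
#'
#' @param ref,alt Reference and alternate allele strings (vectorised).
#' @return Character vector of `"transition"`, `"transversion"`, `"indel"`.
#' @export
classify_substitution <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) abort("empty allele string")
  n <- max(length(ref), length(alt))
  ref <- toupper(rep_len(ref, n)); alt <- toupper(rep_len(alt, n))
  out <- character(n)
  indel <- nchar(ref) != nchar(alt)
  out[indel] <- "indel"
  snp <- !indel & nchar(ref) == 1
  if (any(!indel & nchar(ref) > 1))
    abort("multi-base same-length substitutions are not classifiable")
  bad <- snp & (!(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T")))
  if (any(bad)) abort("ambiguous base code in ref/alt")
  if (any(snp & ref == alt)) abort("ref and alt are identical")
  ts <- snp & paste(ref, alt) %in% c("A G", "G A", "C T", "T C")
  out[ts] <- "transition"
  out[snp & !ts] <- "transversion"
  out
}

#' Summarise the mutational spectrum of a call set
#'
#' Counts transitions, transversions and indels (insertions/deletions are
#' taken from the `kind` column; SNPs are classified from ref/alt) and
#' reports the fraction of each class among all calls. A transition-heavy,
#' indel-rich spectrum is the classic signature of mismatch-repair
#' (mutator) lineages.
#'
#' @param calls Mutation-call data frame.
#' @return Data frame with columns `class`, `count`, `fraction`.
#' @export
spectrum_summary <- function(calls) {
  classes <- c("transition", "transversion", "indel")
  if (nrow(calls) == 0) {
    return(data.frame(class = classes, count = 0L, fraction = NA_real_))
  }
  cls <- ifelse(calls$kind %in% c("insertion", "deletion"), "indel",
                classify_substitution(calls$ref, calls$alt))
  count <- vapply(classes, function(k) sum(cls == k), integer(1))
  data.frame(class = classes, count = count,
             fraction = count / sum(count), row.names = NULL)
}
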