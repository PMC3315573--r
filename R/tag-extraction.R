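TAG_LEN <- 21L
ANCHOR <- "CATG"

checkDna <- function(seq) {
    s <- toupper(as.character(seq))
    if (length(s) != 1L) stop("expected a single sequence")
    if (grepl("[^ACGTN]", s))
        stop("sequence contains characters outside {A,C,G,T,N}")
    s
}

#' Locate NlaIII recognition sites
#'
#' Returns the 1-based position of the `C` of every `CATG` occurrence in a
#' DNA string, ascending. `CATG` cannot overlap itself, but the scan is
#' exhaustive regardless.
#'
#' @param seq A DNA string (character or `DNAString`) over `{A,C,G,T,N}`.
#' @return Integer vector of anchor positions (possibly empty).
#' @examples
#' findNlaIIISites("CATGCATG")  # 1, 5
#' @export
#' @importFrom Biostrings matchPattern
findNlaIIISites <- function(seq) {
    s <- checkDna(seq)
    if (nchar(s) < 4L) return(integer(0))
    m <- Biostrings::matchPattern(ANCHOR, Biostrings::DNAString(s))
    as.integer(Biostrings::start(m))
}

padTag <- function(s, from) {
    # 21-mer starting at the anchor C; read-through into the poly-A tail
    # pads with 'A' when fewer than 17 nt remain downstream
    raw <- substr(s, from, min(nchar(s), from + TAG_LEN - 1L))
    if (nchar(raw) < TAG_LEN)
        raw <- paste0(raw, strrep("A", TAG_LEN - nchar(raw)))
    raw
}

#' Canonical tag of a transcript
#'
#' The 21-bp tag anchored at the most 3' NlaIII site of a transcript
#' (`CATG` plus the next 17 nt). Sites closer than 17 nt to the 3' end are
#' padded with `A`, modelling read-through into the poly-A tail. Returns
#' `NA` when the transcript has no site.
#'
#' @param transcriptSeq Transcript sequence, 5' to 3', sense strand,
#'   without poly-A tail.
#' @return A 21-nt tag string, or `NA_character_`.
#' @examples
#' canonicalTag("AAAACATGTTTTTTTTTTTTTTTTT")
#' @export
canonicalTag <- function(transcriptSeq) {
    s <- checkDna(transcriptSeq)
    sites <- findNlaIIISites(s)
    if (length(sites) == 0L) return(NA_character_)
    padTag(s, sites[length(sites)])
}

#' All expected tags of a transcript
#'
#' One tag per NlaIII site, ranked from the 3' end (rank 1 = most 3', the
#' canonical tag). Under incomplete digestion the site of rank k emits with
#' probability `c(1-c)^(k-1)`, so secondary-rank tags are the expected
#' minority signal.
#'
#' @inheritParams canonicalTag
#' @return A `data.frame` with columns `rank`, `site` (anchor position, 1
#'   -based within the transcript) and `tag`; zero rows when no site exists.
#' @export
allExpectedTags <- function(transcriptSeq) {
    s <- checkDna(transcriptSeq)
    sites <- findNlaIIISites(s)
    if (length(sites) == 0L)
        return(data.frame(rank = integer(0), site = integer(0),
                          tag = character(0)))
    sites <- rev(sites)  # rank 1 = most 3'
    data.frame(rank = seq_along(sites), site = sites,
               tag = vapply(sites, function(p) padTag(s, p), character(1)))
}

#' Construct a TagLibrary
#'
#' @param tags Character vector of distinct 21-nt `CATG`-anchored tags.
#' @param counts Counts `>= 1`, parallel to `tags`.
#' @param condition Condition label.
#' @return A [TagLibrary-class].
#' @export
tagLibrary <- function(tags, counts, condition = "untitled") {
    new("TagLibrary", condition = condition, tags = as.character(tags),
        counts = as.numeric(counts), total = sum(as.numeric(counts)))
}

#' Read / write a tag-count table
#'
#' Plain two-column TSV (`tag`, `count`) with header.
#'
#' @param path File path.
#' @param condition Condition label for the returned library.
#' @return `readTagLibrary`: a [TagLibrary-class]; `writeTagLibrary`:
#'   `path`, invisibly.
#' @export
readTagLibrary <- function(path, condition = basename(path)) {
    if (!file.exists(path)) stop("tag table not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "numeric"))
    if (!all(c("tag", "count") %in% names(df)))
        stop("tag table must have columns 'tag' and 'count': ", path)
    tagLibrary(df$tag, df$count, condition)
}

#' @rdname readTagLibrary
#' @param lib A [TagLibrary-class].
#' @export
writeTagLibrary <- function(lib, path) {
    o <- order(lib@tags)
    utils::write.table(
        data.frame(tag = lib@tags[o], count = lib@counts[o]),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
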