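#' @include AllClasses.R utils.R
NULL

.tagLengths <- function(tags) width(tagSequences(tags))

.tagWeights <- function(tags, weighted) {
    if (weighted) as.numeric(tagCounts(tags)) else
        rep(1, length(tags))
}

#' Length distribution of a tag set
#'
#' @param tags a \linkS4class{TagSet}
#' @param weighted use read counts (default) or distinct tags
#' @param range lengths reported individually (default 15-30); anything
#'   outside is pooled under "other"
#' @return data.frame with columns length (character), count, percent;
#'   percentages are of the total and sum to 100 up to rounding
#' @export
lengthDistribution <- function(tags, weighted = TRUE, range = 15:30) {
    if (length(tags) == 0) stop("empty tag set")
    len <- .tagLengths(tags)
    w <- .tagWeights(tags, weighted)
    lab <- ifelse(len %in% range, as.character(len), "other")
    levs <- c(as.character(range), "other")
    cnt <- vapply(levs, function(l) sum(w[lab == l]), numeric(1))
    if (cnt[["other"]] == 0) {
        cnt <- cnt[names(cnt) != "other"]
        levs <- levs[levs != "other"]
    }
    data.frame(length = levs, count = unname(cnt),
               percent = unname(roundHalfUp(cnt / sum(cnt) * 100, 2)),
               stringsAsFactors = FALSE)
}

.biasRow <- function(seqs, w, pos) {
    bases <- substr(seqs, pos, pos)
    out <- vapply(c("A", "C", "G", "T"), function(b)
        sum(w[bases == b]), numeric(1))
    names(out) <- c("A", "C", "G", "U")
    out
}

#' First-base composition by length class
#'
#' Fraction of tags (or reads, when weighted) starting with each base,
#' per length class.  T is reported as U.
#'
#' @param tags a \linkS4class{TagSet}
#' @param lengths length classes to profile (default 18-26)
#' @param weighted use read counts (default) or distinct tags
#' @return numeric matrix, rows = length classes with support, columns
#'   A/C/G/U; each row sums to 1
#' @export
firstBaseBias <- function(tags, lengths = 18:26, weighted = TRUE) {
    len <- .tagLengths(tags)
    w <- .tagWeights(tags, weighted)
    seqs <- as.character(tagSequences(tags))
    rows <- lapply(lengths, function(l) {
        sel <- len == l
        if (!any(sel)) return(NULL)
        cnt <- .biasRow(seqs[sel], w[sel], 1L)
        cnt / sum(cnt)
    })
    keep <- !vapply(rows, is.null, logical(1))
    if (!any(keep)) stop("no tags in the requested length range")
    m <- do.call(rbind, rows[keep])
    rownames(m) <- as.character(lengths[keep])
    m
}

#' Per-position base composition and consensus for one length class
#'
#' @param tags a \linkS4class{TagSet}
#' @param length the tag length to profile (e.g. 24)
#' @param weighted use read counts (default) or distinct tags
#' @return list with \code{bias} (matrix, rows = positions, columns
#'   A/C/G/U, row-stochastic) and \code{consensus} (RNA-alphabet string;
#'   per-position argmax, ties broken U > A > G > C)
#' @export
positionalBias <- function(tags, length, weighted = TRUE) {
    len <- .tagLengths(tags)
    sel <- len == length
    if (!any(sel)) stop("no tags of length ", length)
    seqs <- as.character(tagSequences(tags))[sel]
    w <- .tagWeights(tags, weighted)[sel]
    m <- t(vapply(seq_len(length), function(p) {
        cnt <- .biasRow(seqs, w, p)
        cnt / sum(cnt)
    }, numeric(4)))
    rownames(m) <- seq_len(length)
    tieOrder <- c("U", "A", "G", "C")
    consensus <- apply(m, 1, function(r) {
        r <- r[tieOrder]
        tieOrder[which.max(r)]   # which.max takes the first maximum
    })
    list(bias = m, consensus = paste(consensus, collapse = ""))
}
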