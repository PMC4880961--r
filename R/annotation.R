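#' @include AllClasses.R utils.R
NULL

#' Build an ordered list of annotation reference sets
#'
#' @param ... named \link[Biostrings]{DNAStringSet} (or character) objects,
#'   one per non-coding RNA class, in priority order, e.g.
#'   \code{referenceSets(rRNA = ..., tRNA = ..., mature_miRNA = ...)}
#' @return named list of DNAStringSet, priority = list order
#' @export
referenceSets <- function(...) {
    refs <- list(...)
    if (length(refs) == 0 || is.null(names(refs)) ||
        any(!nzchar(names(refs))))
        stop("reference sets must be named (class labels)")
    lapply(refs, function(r) {
        r <- DNAStringSet(.toDna(as.character(r)))
        if (length(r) == 0) stop("empty reference set")
        r
    })
}

#' Normalise a mature miRNA name to its family
#'
#' Strips the species prefix, any arm suffix and trailing letter variants:
#' \code{ath-miR157a -> miR157}, \code{ptc-miR408-5p -> miR408}.
#'
#' @param x character vector of miRNA names
#' @return character vector of family names
#' @export
mirnaFamily <- function(x) {
    x <- sub("^[a-z]{3,4}-", "", x)
    x <- sub("-[35]p$", "", x)
    sub("^(miR[0-9]+)[a-z]*$", "\\1", x, ignore.case = TRUE)
}

#' Classify one tag against priority-ordered reference sets
#'
#' The first class (in priority order) whose references contain the tag
#' as a substring with at most \code{max_mm} mismatches wins; a tag
#' matching nothing is "unannotated".  The per-class mismatch allowance
#' defaults to 0 for structural RNA classes and 2 for the mature miRNA
#' catalogue, where imperfect matches are flagged as variants.
#'
#' @param tag a single tag sequence
#' @param refs ordered named list from \code{\link{referenceSets}}
#' @param max_mm named (per class) or scalar mismatch allowance;
#'   \code{NULL} uses 0, except 2 for class "mature_miRNA"
#' @return one-row data.frame: tag, class, reference, mismatches, variant
#' @export
classifyTag <- function(tag, refs, max_mm = NULL) {
    if (length(refs) == 0) stop("empty reference list")
    tag <- .toDna(tag)
    .checkAlphabet(tag, what = "tag")
    mmFor <- function(cls) {
        if (is.null(max_mm))
            return(if (cls == "mature_miRNA") 2L else 0L)
        if (!is.null(names(max_mm)) && cls %in% names(max_mm))
            return(as.integer(max_mm[[cls]]))
        as.integer(max_mm[[1]])
    }
    for (cls in names(refs)) {
        mm <- mmFor(cls)
        rs <- refs[[cls]]
        ok <- which(width(rs) >= nchar(tag))
        for (j in ok) {
            hits <- matchPattern(tag, rs[[j]], max.mismatch = mm,
                                 with.indels = FALSE)
            if (length(hits) > 0) {
                best <- min(vapply(seq_along(hits), function(h)
                    sum(strsplit(as.character(hits[h]), "")[[1]] !=
                        strsplit(tag, "")[[1]]), integer(1)))
                return(data.frame(
                    tag = tag, class = cls,
                    reference = names(rs)[j],
                    mismatches = best,
                    variant = cls == "mature_miRNA" && best >= 1L,
                    stringsAsFactors = FALSE))
            }
        }
    }
    data.frame(tag = tag, class = "unannotated", reference = NA_character_,
               mismatches = NA_integer_, variant = FALSE,
               stringsAsFactors = FALSE)
}

#' Classify every tag of a TagSet
#'
#' @param tags a \linkS4class{TagSet}
#' @param refs,max_mm see \code{\link{classifyTag}}
#' @return data.frame, one row per tag, with the tag's read count attached
#' @export
classifyTags <- function(tags, refs, max_mm = NULL) {
    seqs <- as.character(tagSequences(tags))
    out <- do.call(rbind, lapply(seqs, classifyTag, refs = refs,
                                 max_mm = max_mm))
    out$count <- tagCounts(tags)
    out
}

#' Match a tag against a mature miRNA catalogue with end overhangs
#'
#' Considers every ungapped alignment of the tag against each reference
#' with at most \code{overhang} unaligned bases at either end; mismatches
#' are counted over the opposed positions.  The best match minimises the
#' mismatch count; ties are broken by reference name (lexicographic), then
#' by smaller offset.  One or more mismatches flags a variant of the
#' matched family.
#'
#' @param tag a single tag sequence
#' @param mature_refs named \link[Biostrings]{DNAStringSet} of mature
#'   miRNAs (names like "ath-miR157a")
#' @param max_mm maximum mismatches for a reportable match (default 2)
#' @param overhang maximum unaligned overhang per end (default 2)
#' @return one-row data.frame: tag, family, reference, mismatches,
#'   variant; family NA when nothing matches within \code{max_mm}
#' @export
matchMirbase <- function(tag, mature_refs, max_mm = 2L, overhang = 2L) {
    tag <- .toDna(tag)
    .checkAlphabet(tag, what = "tag")
    tb <- strsplit(tag, "")[[1]]
    lt <- length(tb)
    bestMM <- Inf; bestRef <- NA_character_; bestOff <- NA_integer_
    refNames <- names(mature_refs)
    ord <- order(refNames)
    for (j in ord) {
        rseq <- as.character(mature_refs[[j]])
        rb <- strsplit(rseq, "")[[1]]
        lr <- length(rb)
        if (abs(lt - lr) > overhang) next
        ## offset d: tag position i faces reference position i + d
        for (d in seq.int(-overhang, lr - lt + overhang)) {
            i1 <- max(1L, 1L - d); i2 <- min(lt, lr - d)
            if (i2 < i1) next
            if ((i1 - 1L) > overhang || (lt - i2) > overhang) next
            mm <- sum(tb[i1:i2] != rb[(i1:i2) + d])
            if (mm < bestMM) {
                bestMM <- mm; bestRef <- refNames[j]; bestOff <- d
            }
        }
    }
    if (!is.finite(bestMM) || bestMM > max_mm)
        return(data.frame(tag = tag, family = NA_character_,
                          reference = NA_character_,
                          mismatches = NA_integer_, variant = FALSE,
                          stringsAsFactors = FALSE))
    data.frame(tag = tag, family = mirnaFamily(bestRef),
               reference = bestRef, mismatches = as.integer(bestMM),
               variant = bestMM >= 1L, stringsAsFactors = FALSE)
}

#' Aggregate annotated miRNA tags into family profiles
#'
#' @param records data.frame with columns \code{family}, \code{count} and
#'   optionally \code{tag}; rows with NA family are ignored
#' @param floor families with total count below this are dropped
#'   (default 500, the conventional reporting floor)
#' @return data.frame sorted by total count (descending): family, count,
#'   n_members, representative (highest-count member sequence, when tags
#'   are supplied)
#' @export
aggregateFamilies <- function(records, floor = 500) {
    records <- records[!is.na(records$family), , drop = FALSE]
    if (nrow(records) == 0)
        return(data.frame(family = character(0), count = numeric(0),
                          n_members = integer(0),
                          representative = character(0),
                          stringsAsFactors = FALSE))
    sp <- split(records, records$family)
    out <- do.call(rbind, lapply(sp, function(g) {
        rep_seq <- if ("tag" %in% colnames(g))
            g$tag[which.max(g$count)] else NA_character_
        data.frame(family = g$family[1], count = sum(g$count),
                   n_members = nrow(g), representative = rep_seq,
                   stringsAsFactors = FALSE)
    }))
    out <- out[out$count >= floor, , drop = FALSE]
    out <- out[order(-out$count, out$family), , drop = FALSE]
    rownames(out) <- NULL
    out
}
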