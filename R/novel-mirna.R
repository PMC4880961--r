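#' @include AllClasses.R folding.R
NULL

#' Map tags to a genome by exact matching on both strands
#'
#' @param tags a \linkS4class{TagSet}
#' @param genome named \link[Biostrings]{DNAStringSet} (or FASTA path)
#' @return data.frame: tag, count, chrom, start, end (1-based inclusive),
#'   strand, n_hits (total loci for that tag, for multi-mapper flagging);
#'   minus-strand hits are reverse-complement occurrences, coordinates on
#'   the forward reference
#' @export
mapTags <- function(tags, genome) {
    if (is.character(genome) && length(genome) == 1L)
        genome <- tryCatch(readDNAStringSet(genome),
                           error = function(e)
                               stop("cannot read genome: ",
                                    conditionMessage(e), call. = FALSE))
    seqs <- as.character(tagSequences(tags))
    counts <- tagCounts(tags)
    rows <- list()
    for (i in seq_along(seqs)) {
        for (str in c("+", "-")) {
            pat <- if (str == "+") seqs[i] else .revComp(seqs[i])
            m <- vmatchPattern(pat, genome)
            for (ch in seq_along(m)) {
                ir <- m[[ch]]
                if (length(ir) == 0) next
                rows[[length(rows) + 1L]] <- data.frame(
                    tag = seqs[i], count = counts[i],
                    chrom = names(genome)[ch],
                    start = start(ir), end = end(ir), strand = str,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (length(rows) == 0)
        return(data.frame(tag = character(0), count = integer(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          n_hits = integer(0), stringsAsFactors = FALSE))
    hits <- do.call(rbind, rows)
    hits$n_hits <- as.integer(ave(hits$count, hits$tag, FUN = length))
    hits <- hits[order(hits$chrom, hits$strand, hits$start, hits$end), ]
    rownames(hits) <- NULL
    hits
}

#' Cluster mapped tag hits into blocks by single linkage
#'
#' Hits on the same chromosome and strand are merged while the gap to the
#' running block end is at most \code{max_gap}.
#'
#' @param hits data.frame from \code{\link{mapTags}}
#' @param max_gap maximum gap (nt) within a block (default 200)
#' @return list with \code{blocks} (data.frame: block_id, chrom, strand,
#'   start, end, n_tags, total_count) and \code{members} (the hits with a
#'   block_id column)
#' @export
clusterBlocks <- function(hits, max_gap = 200L) {
    if (nrow(hits) == 0)
        return(list(blocks = data.frame(block_id = integer(0),
                                        chrom = character(0),
                                        strand = character(0),
                                        start = integer(0),
                                        end = integer(0),
                                        n_tags = integer(0),
                                        total_count = numeric(0)),
                    members = cbind(hits, block_id = integer(0))))
    hits <- hits[order(hits$chrom, hits$strand, hits$start, hits$end), ]
    bid <- integer(nrow(hits))
    cur <- 0L; curEnd <- -Inf; curKey <- ""
    for (i in seq_len(nrow(hits))) {
        key <- paste(hits$chrom[i], hits$strand[i])
        if (key != curKey || hits$start[i] - curEnd > max_gap) {
            cur <- cur + 1L
            curKey <- key
            curEnd <- hits$end[i]
        } else curEnd <- max(curEnd, hits$end[i])
        bid[i] <- cur
    }
    hits$block_id <- bid
    blocks <- do.call(rbind, lapply(split(hits, bid), function(g)
        data.frame(block_id = g$block_id[1], chrom = g$chrom[1],
                   strand = g$strand[1], start = min(g$start),
                   end = max(g$end), n_tags = length(unique(g$tag)),
                   total_count = sum(g$count[!duplicated(g$tag)]),
                   stringsAsFactors = FALSE)))
    rownames(blocks) <- NULL
    list(blocks = blocks, members = hits)
}

#' Default thresholds for precursor evaluation
#'
#' @param max_window,min_window hard window bounds (nt); windows below
#'   \code{soft_min_window} fail, those in [soft, min) pass as short
#' @param soft_min_window soft lower bound admitting compact precursors
#' @param mfe_max maximum (most positive) admissible window fold energy,
#'   in builtin-model units
#' @param min_mature_paired minimum mature bases paired in the fold
#' @param max_mature_unpaired maximum mature bases left unpaired
#' @param max_star_span_slack admissible spread of the mature's partner
#'   region beyond the mature length (bulge allowance)
#' @param min_duplex_ratio minimum ratio of the realised mature-pair
#'   energy to the mature's perfect-complement energy; separates a true
#'   mature/star stem from incidental pairing
#' @param window_sizes candidate window lengths tried around the dominant
#'   tag
#' @return named list of thresholds
#' @export
precursorThresholds <- function(max_window = 400L, min_window = 100L,
                                soft_min_window = 74L, mfe_max = -20,
                                min_mature_paired = 14L,
                                max_mature_unpaired = 6L,
                                max_star_span_slack = 4L,
                                min_duplex_ratio = 0.74,
                                window_sizes = c(100L, 160L, 220L, 280L,
                                                 340L, 400L)) {
    list(max_window = max_window, min_window = min_window,
         soft_min_window = soft_min_window, mfe_max = mfe_max,
         min_mature_paired = min_mature_paired,
         max_mature_unpaired = max_mature_unpaired,
         max_star_span_slack = max_star_span_slack,
         min_duplex_ratio = min_duplex_ratio,
         window_sizes = window_sizes[window_sizes <= max_window])
}

## evaluate one window; returns a PrecursorCandidate
.evaluateWindow <- function(winSeq, mature, thresholds, model,
                            id, chrom, strand, wStart, wEnd, matureCount) {
    T <- nchar(winSeq)
    verdicts <- c(window_length = FALSE, mature_in_window = FALSE,
                  mfe = FALSE, mature_paired = FALSE,
                  mature_unpaired = FALSE, star_contiguous = FALSE,
                  loop_excludes_mature = FALSE, duplex_energy = FALSE)
    mk <- function(struct, star, arm, verdicts)
        new("PrecursorCandidate", id = id, chrom = chrom, strand = strand,
            windowStart = as.integer(wStart), windowEnd = as.integer(wEnd),
            seq = winSeq, structure = struct, mature = mature, star = star,
            arm = arm, matureCount = as.integer(matureCount),
            verdicts = verdicts, accepted = all(verdicts))
    emptyStruct <- new("SecondaryStructure", seq = winSeq,
                       dotBracket = strrep(".", T),
                       partner = integer(T), energy = 0)
    verdicts["window_length"] <- T >= thresholds$soft_min_window &&
        T <= thresholds$max_window
    mpos <- regexpr(mature, winSeq, fixed = TRUE)[1]
    verdicts["mature_in_window"] <- mpos > 0
    if (!verdicts["window_length"] || !verdicts["mature_in_window"])
        return(mk(emptyStruct, "", "NA", verdicts))

    struct <- foldHairpin(winSeq, model)
    verdicts["mfe"] <- foldEnergy(struct) <= thresholds$mfe_max
    L <- nchar(mature)
    m1 <- mpos; m2 <- mpos + L - 1L
    q <- struct@partner[m1:m2]
    nPaired <- sum(q > 0L)
    verdicts["mature_paired"] <- nPaired >= thresholds$min_mature_paired
    verdicts["mature_unpaired"] <-
        (L - nPaired) <= thresholds$max_mature_unpaired
    star <- ""; arm <- "NA"
    if (nPaired > 0L) {
        P <- q[q > 0L]
        span <- max(P) - min(P) + 1L
        verdicts["star_contiguous"] <-
            span <= L + thresholds$max_star_span_slack
        ## partners entirely outside the mature itself (a mature folding
        ## onto itself would straddle the hairpin loop)
        verdicts["loop_excludes_mature"] <-
            max(P) < m1 || min(P) > m2
        s1 <- min(P) + 2L; s2 <- s1 + L - 1L
        if (s1 >= 1L && s2 <= T) star <- substr(winSeq, s1, s2)
        arm <- if (m1 < min(P)) "5p" else "3p"
        ## energy of the realised mature pairs vs the perfect complement
        b <- strsplit(winSeq, "")[[1]]
        pe <- model@pairEnergies
        realised <- sum(vapply(which(q > 0L), function(k) {
            a <- b[m1 + k - 1L]; d <- b[q[k]]
            if ((a == "G" && d == "C") || (a == "C" && d == "G"))
                pe[["GC"]]
            else if ((a == "A" && d == "T") || (a == "T" && d == "A"))
                pe[["AU"]]
            else pe[["GU"]]
        }, numeric(1)))
        perfect <- perfectDuplexEnergy(mature, model)
        verdicts["duplex_energy"] <-
            abs(realised) / abs(perfect) >= thresholds$min_duplex_ratio
    }
    mk(struct, star, arm, verdicts)
}

#' Evaluate a mapped block as a candidate miRNA precursor
#'
#' The dominant tag (highest count; ties by sequence) defines the mature
#' candidate.  Genomic windows of several lengths centred on the dominant
#' tag are extracted (reverse-complemented for minus-strand blocks),
#' folded under the energy model and checked against the hairpin
#' criteria: admissible window length; fold energy at most
#' \code{mfe_max}; at least \code{min_mature_paired} mature bases paired
#' and at most \code{max_mature_unpaired} unpaired; the mature's partner
#' region contiguous (a genuine mature/star duplex, spread at most the
#' mature length plus \code{max_star_span_slack}); the mature outside
#' the hairpin loop (it must not pair with itself); and the realised
#' mature-pair energy at least \code{min_duplex_ratio} of the mature's
#' perfect-complement energy.  The star sequence is
#' read off the partner region with the 2-nt 3' overhang convention; the
#' arm is 5p when the mature lies before its partner region.  The
#' accepted candidate with the lowest fold energy is returned, or the
#' best-scoring rejected window with its failed verdicts.
#'
#' @param block one row of \code{blocks} from \code{\link{clusterBlocks}}
#' @param members the member hits of that block
#' @param genome named DNAStringSet
#' @param model an \linkS4class{EnergyModel}
#' @param thresholds list from \code{\link{precursorThresholds}}
#' @return a \linkS4class{PrecursorCandidate}
#' @export
evaluatePrecursor <- function(block, members, genome,
                              model = energyModel(),
                              thresholds = precursorThresholds()) {
    stopifnot(nrow(block) == 1L)
    members <- members[members$block_id == block$block_id, , drop = FALSE]
    o <- order(-members$count, members$tag)
    dom <- members[o[1L], ]
    chromSeq <- genome[[block$chrom]]
    chromLen <- length(chromSeq)
    span <- block$end - block$start + 1L
    if (span > thresholds$max_window) {
        st <- new("SecondaryStructure", seq = "", dotBracket = "",
                  partner = integer(0), energy = 0)
        return(new("PrecursorCandidate", id = "rejected",
                   chrom = block$chrom, strand = block$strand,
                   windowStart = as.integer(block$start),
                   windowEnd = as.integer(block$end), seq = "",
                   structure = st, mature = dom$tag, star = "",
                   arm = "NA", matureCount = as.integer(dom$count),
                   verdicts = c(window_length = FALSE),
                   accepted = FALSE))
    }
    centre <- (dom$start + dom$end) %/% 2L
    best <- NULL; bestRejected <- NULL
    tried <- character(0)
    for (W in thresholds$window_sizes) {
        ## the mature may sit on either arm, i.e. near either end of the
        ## precursor: try left-anchored, centred and right-anchored windows
        starts <- unique(pmax(1L, c(dom$start - 10L,
                                    centre - W %/% 2L,
                                    dom$end + 10L - W + 1L)))
        for (ws in starts) {
        we <- min(chromLen, ws + W - 1L)
        ws <- max(1L, we - W + 1L)
        key <- paste(ws, we)
        if (key %in% tried) next
        tried <- c(tried, key)
        winSeq <- as.character(subseq(chromSeq, ws, we))
        if (block$strand == "-") winSeq <- .revComp(winSeq)
        cand <- .evaluateWindow(winSeq, dom$tag, thresholds, model,
                                id = sprintf("block%d", block$block_id),
                                chrom = block$chrom,
                                strand = block$strand,
                                wStart = ws, wEnd = we,
                                matureCount = dom$count)
        if (cand@accepted) {
            ## prefer the most compact accepted hairpin, then lower energy
            if (is.null(best) ||
                nchar(cand@seq) < nchar(best@seq) ||
                (nchar(cand@seq) == nchar(best@seq) &&
                 foldEnergy(cand@structure) < foldEnergy(best@structure)))
                best <- cand
        } else if (is.null(bestRejected) ||
                   sum(cand@verdicts) > sum(bestRejected@verdicts)) {
            bestRejected <- cand
        }
        }
        if (!is.null(best)) break  # window sizes ascend; stop at smallest
    }
    if (!is.null(best)) best else bestRejected
}

#' Call novel miRNAs from unannotated tags and a genome
#'
#' Maps the tags exactly (both strands), clusters hits into blocks,
#' evaluates each block's window as a hairpin precursor and reports one
#' row per accepted candidate, with the mature sequence placed in the
#' column of its arm (the other arm column is "-"), following the usual
#' novel-miRNA table layout.
#'
#' @param tags a \linkS4class{TagSet}; when \code{annotations} is given,
#'   only tags classified "unannotated" are used
#' @param genome named DNAStringSet or FASTA path
#' @param annotations optional data.frame from \code{\link{classifyTags}}
#' @param model an \linkS4class{EnergyModel}
#' @param thresholds list from \code{\link{precursorThresholds}}
#' @param max_gap block clustering distance (nt)
#' @return list with \code{calls} (data.frame: id, chrom, start, end,
#'   strand, arm, seq_5p, seq_3p, star, count, precursor_length, mfe) and
#'   \code{candidates} (all evaluated \linkS4class{PrecursorCandidate}s)
#' @export
callNovelMirnas <- function(tags, genome, annotations = NULL,
                            model = energyModel(),
                            thresholds = precursorThresholds(),
                            max_gap = 200L) {
    if (is.character(genome) && length(genome) == 1L)
        genome <- readDNAStringSet(genome)
    if (!is.null(annotations)) {
        keep <- annotations$tag[annotations$class == "unannotated"]
        sel <- as.character(tagSequences(tags)) %in% keep
        tags <- tagSet(as.character(tagSequences(tags))[sel],
                       tagCounts(tags)[sel])
    }
    empty <- data.frame(id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), arm = character(0),
                        seq_5p = character(0), seq_3p = character(0),
                        star = character(0), count = integer(0),
                        precursor_length = integer(0), mfe = numeric(0),
                        stringsAsFactors = FALSE)
    if (length(tags) == 0)
        return(list(calls = empty, candidates = list()))
    hits <- mapTags(tags, genome)
    cl <- clusterBlocks(hits, max_gap = max_gap)
    cands <- lapply(seq_len(nrow(cl$blocks)), function(i)
        evaluatePrecursor(cl$blocks[i, , drop = FALSE], cl$members,
                          genome, model, thresholds))
    acc <- Filter(function(x) isTRUE(x@accepted), cands)
    if (length(acc) == 0) return(list(calls = empty, candidates = cands))
    ## a hairpin carries the mature's reverse complement on its other arm,
    ## so the same locus is typically hit on both strands: keep one call
    ## per overlapping genomic window (highest count, then lowest energy,
    ## then plus strand)
    o <- order(-vapply(acc, function(x) as.numeric(x@matureCount),
                       numeric(1)),
               vapply(acc, function(x) foldEnergy(x@structure),
                      numeric(1)),
               vapply(acc, function(x) x@strand != "+", logical(1)),
               vapply(acc, function(x) x@windowStart, integer(1)))
    acc <- acc[o]
    kept <- list()
    for (x in acc) {
        clash <- any(vapply(kept, function(k)
            k@chrom == x@chrom && x@windowStart <= k@windowEnd &&
                k@windowStart <= x@windowEnd, logical(1)))
        if (!clash) kept[[length(kept) + 1L]] <- x
    }
    acc <- kept
    calls <- do.call(rbind, lapply(seq_along(acc), function(i) {
        x <- acc[[i]]
        data.frame(id = sprintf("novel%02d", i), chrom = x@chrom,
                   start = x@windowStart, end = x@windowEnd,
                   strand = x@strand, arm = x@arm,
                   seq_5p = if (x@arm == "5p") x@mature else "-",
                   seq_3p = if (x@arm == "3p") x@mature else "-",
                   star = x@star, count = x@matureCount,
                   precursor_length = nchar(x@seq),
                   mfe = foldEnergy(x@structure),
                   stringsAsFactors = FALSE)
    }))
    list(calls = calls, candidates = cands)
}
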