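#' @include AllClasses.R folding.R
NULL

.STATUS_SCORE <- c(match = 0, wobble = 0.5, mismatch = 1, gap = 1)

## score an ungapped alignment of miRNA bases (mb) against the reversed
## site bases (rs), both same length
.scoreUngapped <- function(mb, rs, model) {
    status <- .pairClass(mb, rs)
    energy <- sum(.pairEnergyChar(mb, rs, model))
    list(status = status, energy = energy, bulgeAfter = 0L)
}

#' Score one miRNA/target duplex positionally
#'
#' The site is the transcript region opposite the miRNA (given 5'->3' in
#' transcript sense) and is reverse-oriented for antiparallel pairing:
#' miRNA position p faces the p-th base of the reversed site.  Each
#' position is a Watson-Crick match, a G:U wobble (0.5 mismatch), or a
#' mismatch (1.0).  A site one base longer or shorter is handled as a
#' single 1-nt bulge scored 1.0: the bulge placement minimising the total
#' score is chosen (ties to the 5'-most placement).  Larger length
#' differences are an error.
#'
#' @param mirna miRNA sequence 5'->3'
#' @param site target site 5'->3' (transcript sense); length within 1 of
#'   the miRNA
#' @param model an \linkS4class{EnergyModel} for the duplex energies
#' @return a \linkS4class{DuplexScore}
#' @export
scoreDuplex <- function(mirna, site, model = energyModel()) {
    mirna <- .toDna(mirna); site <- .toDna(site)
    .checkAlphabet(mirna, what = "miRNA")
    .checkAlphabet(site, what = "target site")
    Lm <- nchar(mirna); Ls <- nchar(site)
    if (abs(Lm - Ls) > 1L)
        stop("site length may differ from the miRNA by at most 1 nt")
    mb <- strsplit(mirna, "")[[1]]
    rs <- rev(strsplit(site, "")[[1]])

    if (Ls == Lm) {
        al <- .scoreUngapped(mb, rs, model)
        status <- al$status
        energy <- al$energy
        bulgeAfter <- 0L
        gapExtra <- 0
    } else if (Ls == Lm + 1L) {
        ## one target base bulged out; try every placement
        best <- NULL
        for (b in 0:Lm) {
            keep <- rs[setdiff(seq_len(Ls), b + 1L)]
            al <- .scoreUngapped(mb, keep, model)
            tot <- sum(.STATUS_SCORE[al$status]) + 1
            if (is.null(best) || tot < best$tot) {
                best <- list(al = al, tot = tot, b = b)
            }
        }
        status <- best$al$status
        energy <- best$al$energy
        bulgeAfter <- as.integer(best$b)
        gapExtra <- 1
    } else {
        ## one miRNA base unopposed (gap status at that position)
        best <- NULL
        for (b in seq_len(Lm)) {
            opp <- character(Lm)
            opp[setdiff(seq_len(Lm), b)] <- rs
            st <- .pairClass(mb, ifelse(opp == "", "N", opp))
            st[b] <- "gap"
            en <- sum(.pairEnergyChar(mb[-b], rs, model))
            tot <- sum(.STATUS_SCORE[st])
            if (is.null(best) || tot < best$tot)
                best <- list(status = st, energy = en, tot = tot, b = b)
        }
        status <- best$status
        energy <- best$energy
        bulgeAfter <- 0L
        gapExtra <- 0
    }

    pos <- seq_len(Lm)
    sc <- .STATUS_SCORE[status]
    bulgeIn <- function(lo, hi)
        if (bulgeAfter >= lo && bulgeAfter >= 1L && bulgeAfter < hi)
            1 else 0
    total <- sum(sc) + gapExtra
    w112 <- sum(sc[pos >= 1 & pos <= min(12L, Lm)]) + bulgeIn(1L, 12L)
    w212 <- sum(sc[pos >= 2 & pos <= min(12L, Lm)]) + bulgeIn(2L, 12L)
    new("DuplexScore", mirna = mirna, site = site,
        status = unname(status), targetBulgeAfter = bulgeAfter,
        total = total, window1to12 = w112, window2to12 = w212,
        duplexEnergy = energy,
        perfectEnergy = perfectDuplexEnergy(mirna, model))
}

#' Apply the six acceptance rules to a scored duplex
#'
#' The rules, applied to the positional mismatch accounting (positions
#' 1-based from the miRNA 5' end, G:U wobble scored 0.5, gaps 1.0):
#' \enumerate{
#'   \item total mismatch score below 4;
#'   \item no two adjacent mismatch positions anywhere in the duplex;
#'   \item no adjacent mismatches within positions 2-12;
#'   \item no mismatch score at positions 10-11 (wobbles and bulges there
#'     also violate this cleavage-site rule unless
#'     \code{rule4_allow_wobble});
#'   \item mismatch score over positions 1-12 strictly below 2.5;
#'   \item duplex energy at least 74 percent of the perfect-complement
#'     energy.
#' }
#' For adjacency (rules 2-3), gap positions count as mismatch-like;
#' wobbles do not.
#'
#' @param score a \linkS4class{DuplexScore}
#' @param rule4_allow_wobble tolerate G:U wobbles at positions 10-11
#' @param energy_ratio_min rule-6 threshold (default 0.74)
#' @return list with \code{accepted} and \code{verdicts} (named logical,
#'   length 6)
#' @export
applyRules <- function(score, rule4_allow_wobble = FALSE,
                       energy_ratio_min = 0.74) {
    st <- score@status
    sc <- .STATUS_SCORE[st]
    Lm <- length(st)
    mmLike <- st %in% c("mismatch", "gap")
    adj <- which(mmLike[-Lm] & mmLike[-1L])  # position of the left member
    r1 <- score@total < 4
    r2 <- length(adj) == 0L
    r3 <- !any(adj >= 2L & (adj + 1L) <= 12L)
    p1011 <- intersect(10:11, seq_len(Lm))
    sc1011 <- sum(sc[p1011])
    if (rule4_allow_wobble)
        sc1011 <- sum(sc[p1011][st[p1011] != "wobble"])
    bulge1011 <- score@targetBulgeAfter %in% c(10L)  # bulge between 10/11
    r4 <- sc1011 == 0 && !bulge1011
    r5 <- score@window1to12 < 2.5
    r6 <- mfeRatio(score@duplexEnergy, score@perfectEnergy) >=
        energy_ratio_min
    verdicts <- c(total_lt4 = r1, no_adjacent_mm = r2,
                  no_adjacent_mm_2_12 = r3, clean_10_11 = r4,
                  window_1_12_lt2.5 = r5, energy_ge_74pct = r6)
    list(accepted = all(verdicts), verdicts = verdicts)
}

#' Scan transcripts for accepted miRNA target sites
#'
#' Slides a window of the miRNA length (and, in bulge mode, length plus
#' and minus one) along the sense strand of each transcript, scores every
#' window with \code{\link{scoreDuplex}} and filters with
#' \code{\link{applyRules}}.
#'
#' @param mirna miRNA sequence 5'->3'
#' @param transcripts named \link[Biostrings]{DNAStringSet} or character
#'   vector, or FASTA path
#' @param model an \linkS4class{EnergyModel}
#' @param step window step (default 1)
#' @param bulge also scan windows one base longer/shorter (default FALSE)
#' @param all return every window with its verdicts instead of accepted
#'   hits only
#' @param ... passed to \code{applyRules}
#' @return data.frame: mirna, transcript, start, end, score, ratio, the
#'   six verdict columns and accepted
#' @export
scanTranscripts <- function(mirna, transcripts, model = energyModel(),
                            step = 1L, bulge = FALSE, all = FALSE, ...) {
    if (is.character(transcripts) && length(transcripts) == 1L &&
        file.exists(transcripts))
        transcripts <- readDNAStringSet(transcripts)
    tx <- as.character(transcripts)
    if (length(tx) == 0) stop("no transcripts supplied")
    if (is.null(names(tx)))
        names(tx) <- sprintf("tx%d", seq_along(tx))
    mirna <- .toDna(mirna)
    Lm <- nchar(mirna)
    widths <- if (bulge) c(Lm, Lm - 1L, Lm + 1L) else Lm
    rows <- list()
    for (t in seq_along(tx)) {
        s <- .toDna(tx[[t]])
        for (W in widths) {
            if (nchar(s) < W) {
                if (W == Lm)
                    warning("transcript '", names(tx)[t],
                            "' shorter than the miRNA; skipped")
                next
            }
            for (st in seq.int(1L, nchar(s) - W + 1L, by = step)) {
                site <- substr(s, st, st + W - 1L)
                ds <- scoreDuplex(mirna, site, model)
                rl <- applyRules(ds, ...)
                if (!all && !rl$accepted) next
                v <- as.list(rl$verdicts)
                rows[[length(rows) + 1L]] <- data.frame(
                    mirna = mirna, transcript = names(tx)[t],
                    start = st, end = st + W - 1L,
                    score = ds@total,
                    ratio = mfeRatio(ds@duplexEnergy, ds@perfectEnergy),
                    as.data.frame(v), accepted = rl$accepted,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (length(rows) == 0)
        return(data.frame(mirna = character(0), transcript = character(0),
                          start = integer(0), end = integer(0),
                          score = numeric(0), ratio = numeric(0),
                          accepted = logical(0), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
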