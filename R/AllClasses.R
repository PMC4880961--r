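#' @include AllGenerics.R
NULL

.CLEAN_CATEGORIES <- c("adapter3_null", "insert_null", "adapter5_contam",
                       "short_lt18", "polyA", "clean")

## ---------------------------------------------------------------------------
## EnergyModel
## ---------------------------------------------------------------------------

#' Per-pair folding energy model
#'
#' A deliberately simple, fully reproducible energy model for hairpin and
#' duplex folding: each base pair contributes a fixed energy (G:C, A:U and
#' the G:U wobble), unpaired bases contribute nothing, and hairpin loops
#' must enclose at least \code{minLoop} unpaired bases.  There are no
#' stacking, bulge or loop terms, so every energy is a small exact sum and
#' every result can be checked by exhaustive enumeration.  Nearest-neighbour
#' thermodynamic values from external folding engines are therefore not
#' comparable with energies produced under this model.
#'
#' @slot pairEnergies named numeric, energies (negative) for "GC", "AU", "GU"
#' @slot minLoop integer, minimum number of unpaired bases in a hairpin loop
#' @export
setClass("EnergyModel",
         representation(pairEnergies = "numeric", minLoop = "integer"))

setValidity("EnergyModel", function(object) {
    pe <- object@pairEnergies
    if (!all(c("GC", "AU", "GU") %in% names(pe)))
        return("pairEnergies must be named 'GC', 'AU', 'GU'")
    if (any(pe >= 0))
        return("all pair energies must be negative")
    if (object@minLoop < 0L)
        return("minLoop must be >= 0")
    TRUE
})

#' @describeIn EnergyModel-class constructor with the package defaults
#'   (G:C -3, A:U -2, G:U -1, minimum loop 3)
#' @param GC,AU,GU pair energies (negative)
#' @param minLoop minimum hairpin loop length in bases
#' @export
energyModel <- function(GC = -3, AU = -2, GU = -1, minLoop = 3L) {
    new("EnergyModel",
        pairEnergies = c(GC = GC, AU = AU, GU = GU),
        minLoop = as.integer(minLoop))
}

setMethod("show", "EnergyModel", function(object) {
    pe <- object@pairEnergies
    cat("EnergyModel: GC", pe[["GC"]], " AU", pe[["AU"]],
        " GU", pe[["GU"]], " minLoop", object@minLoop, "\n")
})

## ---------------------------------------------------------------------------
## SecondaryStructure
## ---------------------------------------------------------------------------

#' Predicted secondary structure of a single RNA sequence
#'
#' Holds a non-crossing (pseudoknot-free) structure as a dot-bracket string,
#' a per-base partner vector and the total energy under the
#' \linkS4class{EnergyModel} that produced it.
#'
#' @slot seq character, the folded sequence (DNA alphabet, T for U)
#' @slot dotBracket character, dot-bracket notation, same length as seq
#' @slot partner integer vector, 1-based partner index per base (0 = unpaired)
#' @slot energy numeric, total structure energy (<= 0)
#' @export
setClass("SecondaryStructure",
         representation(seq = "character", dotBracket = "character",
                        partner = "integer", energy = "numeric"))

setValidity("SecondaryStructure", function(object) {
    n <- nchar(object@seq)
    if (nchar(object@dotBracket) != n)
        return("dot-bracket length differs from sequence length")
    if (length(object@partner) != n)
        return("partner vector length differs from sequence length")
    p <- object@partner
    idx <- which(p > 0L)
    if (!all(p[p[idx]] == idx))
        return("partner vector is not symmetric")
    if (object@energy > 1e-9)
        return("energy must be <= 0")
    TRUE
})

#' @describeIn SecondaryStructure-class the dot-bracket string
#' @param x a SecondaryStructure
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x) x@dotBracket)

#' @describeIn SecondaryStructure-class two-column matrix of pairs (i < j)
#' @export
setMethod("structurePairs", "SecondaryStructure", function(x) {
    i <- which(x@partner > seq_along(x@partner))
    cbind(i = i, j = x@partner[i])
})

#' @describeIn SecondaryStructure-class the structure energy
#' @export
setMethod("foldEnergy", "SecondaryStructure", function(x) x@energy)

setMethod("show", "SecondaryStructure", function(object) {
    cat("SecondaryStructure (", nchar(object@seq), " nt, ",
        sum(object@partner > 0L) / 2, " pairs, energy ",
        object@energy, ")\n", sep = "")
    cat(" ", object@seq, "\n ", object@dotBracket, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## CleaningReport
## ---------------------------------------------------------------------------

#' Read-cleaning accounting report
#'
#' Counts for the raw input, the high-quality subset, the five removal
#' categories and the surviving clean reads.  Percentages are relative to
#' the high-quality count and rounded half-up to two decimals, matching the
#' arithmetic of published sequencing summary tables.
#'
#' @slot counts named numeric vector with elements \code{total_raw},
#'   \code{high_quality}, \code{adapter3_null}, \code{insert_null},
#'   \code{adapter5_contam}, \code{short_lt18}, \code{polyA}, \code{clean}
#' @export
setClass("CleaningReport", representation(counts = "numeric"))

setValidity("CleaningReport", function(object) {
    cts <- object@counts
    need <- c("total_raw", "high_quality", .CLEAN_CATEGORIES)
    if (!all(need %in% names(cts)))
        return(paste("missing counts:",
                     paste(setdiff(need, names(cts)), collapse = ", ")))
    if (any(cts < 0)) return("counts must be >= 0")
    if (abs(sum(cts[.CLEAN_CATEGORIES]) - cts[["high_quality"]]) > 0.5)
        return("category counts do not sum to the high-quality count")
    if (cts[["total_raw"]] < cts[["high_quality"]])
        return("total_raw cannot be smaller than high_quality")
    TRUE
})

#' @describeIn CleaningReport-class the raw counts
#' @param x a CleaningReport
#' @export
setMethod("cleaningCounts", "CleaningReport", function(x) x@counts)

#' @describeIn CleaningReport-class percentages of the high-quality count,
#'   rounded half-up to 2 decimals (the raw total is reported as NA)
#' @export
setMethod("cleaningPercentages", "CleaningReport", function(x) {
    cts <- x@counts
    hq <- cts[["high_quality"]]
    pct <- roundHalfUp(cts / hq * 100, 2)
    pct[["total_raw"]] <- NA_real_
    pct
})

setMethod("show", "CleaningReport", function(object) {
    df <- as.data.frame(object)
    cat("CleaningReport\n")
    print(df, row.names = FALSE)
})

#' Render a CleaningReport as a data.frame
#'
#' @param x a \linkS4class{CleaningReport}
#' @param row.names,optional,... ignored, present for generic consistency
#' @return data.frame with columns read_type, count, percent
#' @method as.data.frame CleaningReport
#' @export
as.data.frame.CleaningReport <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    cts <- cleaningCounts(x)
    ord <- c("total_raw", "high_quality", "adapter3_null", "insert_null",
             "adapter5_contam", "short_lt18", "polyA", "clean")
    data.frame(read_type = ord, count = unname(cts[ord]),
               percent = unname(cleaningPercentages(x)[ord]),
               stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## TagSet
## ---------------------------------------------------------------------------

#' Unique small RNA tags with read counts
#'
#' The non-redundant representation of a cleaned library: each distinct
#' sequence appears once, carrying the number of reads collapsed into it.
#' Tags are ordered by decreasing count, ties by sequence.
#'
#' @slot seqs a \link[Biostrings]{DNAStringSet} of distinct tag sequences
#' @slot counts integer read counts, parallel to \code{seqs}
#' @export
setClass("TagSet",
         representation(seqs = "DNAStringSet", counts = "integer"))

setValidity("TagSet", function(object) {
    if (length(object@seqs) != length(object@counts))
        return("seqs and counts differ in length")
    if (any(object@counts < 1L)) return("counts must be >= 1")
    if (anyDuplicated(as.character(object@seqs)))
        return("tag sequences must be distinct")
    TRUE
})

#' @describeIn TagSet-class tag sequences as a DNAStringSet
#' @param x a TagSet
#' @export
setMethod("tagSequences", "TagSet", function(x) x@seqs)

#' @describeIn TagSet-class integer read counts per tag
#' @export
setMethod("tagCounts", "TagSet", function(x) x@counts)

#' @describeIn TagSet-class number of distinct tags
#' @export
setMethod("length", "TagSet", function(x) length(x@seqs))

setMethod("show", "TagSet", function(object) {
    cat("TagSet with ", length(object), " unique tags (",
        sum(object@counts), " reads)\n", sep = "")
    n <- min(5L, length(object))
    if (n > 0L) {
        s <- as.character(object@seqs[seq_len(n)])
        cat(paste0("  ", s, "  x", object@counts[seq_len(n)],
                   collapse = "\n"), "\n")
        if (length(object) > n) cat("  ...\n")
    }
})

#' Construct a TagSet directly from sequences and counts
#'
#' Most users obtain a TagSet from \code{\link{collapseUnique}}; this
#' constructor serves programmatic use (e.g. spiking fixtures).
#'
#' @param seqs character vector or DNAStringSet of distinct sequences
#' @param counts integer read counts (default all 1)
#' @return a \linkS4class{TagSet}, sorted by (count desc, sequence asc)
#' @export
tagSet <- function(seqs, counts = rep(1L, length(seqs))) {
    seqs <- as.character(seqs)
    o <- order(-as.integer(counts), seqs)
    new("TagSet", seqs = DNAStringSet(seqs[o]),
        counts = as.integer(counts)[o])
}

## ---------------------------------------------------------------------------
## DuplexScore
## ---------------------------------------------------------------------------

#' Positional mismatch accounting for one miRNA/target duplex
#'
#' Positions are 1-based from the miRNA 5' end.  Each position is a
#' match, a G:U wobble (0.5 mismatch), a mismatch (1.0) or a gap (1.0,
#' a 1-nt bulge).  An extra target-side bulge, if present, is recorded
#' with the miRNA position it follows and also scores 1.0.
#'
#' @slot mirna character, miRNA sequence 5'->3'
#' @slot site character, target site sequence 5'->3' (transcript sense)
#' @slot status character vector per miRNA position:
#'   "match", "wobble", "mismatch" or "gap"
#' @slot targetBulgeAfter integer, miRNA position after which a target-side
#'   bulged base sits (0 = none)
#' @slot total numeric, total mismatch score
#' @slot window1to12,window2to12 numeric, windowed mismatch scores
#' @slot duplexEnergy,perfectEnergy numeric, duplex energy and the energy of
#'   the miRNA bound to its perfect complement under the same model
#' @export
setClass("DuplexScore",
         representation(mirna = "character", site = "character",
                        status = "character",
                        targetBulgeAfter = "integer",
                        total = "numeric",
                        window1to12 = "numeric", window2to12 = "numeric",
                        duplexEnergy = "numeric", perfectEnergy = "numeric"))

setValidity("DuplexScore", function(object) {
    if (length(object@status) != nchar(object@mirna))
        return("status length differs from miRNA length")
    if (!all(object@status %in% c("match", "wobble", "mismatch", "gap")))
        return("invalid position status")
    TRUE
})

#' @describeIn DuplexScore-class per-position status vector
#' @param x a DuplexScore
#' @export
setMethod("duplexStatus", "DuplexScore", function(x) x@status)

#' @describeIn DuplexScore-class total mismatch score
#' @export
setMethod("duplexTotal", "DuplexScore", function(x) x@total)

setMethod("show", "DuplexScore", function(object) {
    sym <- c(match = "|", wobble = "o", mismatch = " ", gap = "-")
    cat("DuplexScore  total ", object@total,
        "  [1-12] ", object@window1to12,
        "  E ", object@duplexEnergy, "/", object@perfectEnergy, "\n",
        sep = "")
    cat(" miRNA 5' ", object@mirna, " 3'\n          ",
        paste(sym[object@status], collapse = ""), "\n",
        " site  3' ", paste(rev(strsplit(object@site, "")[[1]]),
                            collapse = ""), " 5'\n", sep = "")
})

## ---------------------------------------------------------------------------
## PrecursorCandidate
## ---------------------------------------------------------------------------

#' Candidate miRNA precursor evaluated against hairpin criteria
#'
#' @slot id character, candidate identifier
#' @slot chrom,strand character, genomic location of the window
#' @slot windowStart,windowEnd integer, 1-based inclusive genome coordinates
#' @slot seq character, window sequence 5'->3' (minus-strand windows are
#'   reverse-complemented)
#' @slot structure the folded \linkS4class{SecondaryStructure}
#' @slot mature,star character, mature and star sequences 5'->3'
#' @slot arm character, "5p" or "3p"
#' @slot matureCount integer, read count of the mature tag
#' @slot verdicts named logical, one entry per acceptance criterion
#' @slot accepted logical, TRUE iff all verdicts pass
#' @export
setClass("PrecursorCandidate",
         representation(id = "character", chrom = "character",
                        strand = "character",
                        windowStart = "integer", windowEnd = "integer",
                        seq = "character", structure = "SecondaryStructure",
                        mature = "character", star = "character",
                        arm = "character", matureCount = "integer",
                        verdicts = "logical", accepted = "logical"))

setMethod("show", "PrecursorCandidate", function(object) {
    cat("PrecursorCandidate ", object@id, " [", object@chrom, ":",
        object@windowStart, "-", object@windowEnd, " (", object@strand,
        ")]  ", if (object@accepted) "ACCEPTED" else "rejected", "\n",
        sep = "")
    cat("  mature (", object@arm, ", x", object@matureCount, "): ",
        object@mature, "\n  star: ", object@star, "\n  MFE: ",
        foldEnergy(object@structure), "\n", sep = "")
    v <- object@verdicts
    cat("  verdicts: ",
        paste(names(v), ifelse(v, "pass", "FAIL"), sep = "=",
              collapse = " "), "\n", sep = "")
})
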