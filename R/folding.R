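#' @include AllClasses.R
NULL

.BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L, U = 3L)

#' Fold a sequence into its minimum-energy hairpin structure
#'
#' Computes the minimum-energy non-crossing secondary structure under the
#' per-pair \linkS4class{EnergyModel} by dynamic programming (a
#' Nussinov-style recursion with pair energies instead of pair counts).
#' The traceback is deterministic: among co-optimal structures the leftmost
#' unresolved base is paired whenever possible, to its largest co-optimal
#' partner.
#'
#' @param seq a single DNA/RNA string (A/C/G/T/U), 1-500 nt
#' @param model an \linkS4class{EnergyModel}; defaults to the package model
#' @return a \linkS4class{SecondaryStructure}
#' @examples
#' foldHairpin("GGGAAACCC")   # (((...))), energy -9
#' @export
foldHairpin <- function(seq, model = energyModel()) {
    seq <- .toDna(seq)
    .checkAlphabet(seq, what = "fold input")
    n <- nchar(seq)
    if (n < 1 || n > 500)
        stop("foldHairpin expects sequences of 1-500 nt, got ", n)
    code <- unname(.BASE_CODE[strsplit(seq, "")[[1]]])
    pe <- model@pairEnergies
    res <- nussinov_fold(code, pe[["GC"]], pe[["AU"]], pe[["GU"]],
                         model@minLoop)
    partner <- as.integer(res$pairs)
    db <- rep(".", n)
    db[partner > seq_len(n)] <- "("
    db[partner > 0L & partner < seq_len(n)] <- ")"
    new("SecondaryStructure", seq = seq,
        dotBracket = paste(db, collapse = ""),
        partner = partner, energy = as.numeric(res$energy))
}

#' Intermolecular duplex energy of a miRNA bound to a target site
#'
#' The site (given 5'->3' in transcript sense) is reverse-oriented for
#' antiparallel pairing, so miRNA position p faces site position
#' \code{L - p + 1}.  Each opposed A:U, G:C or G:U pair contributes its
#' model energy; every other opposition contributes 0.  No intramolecular
#' structure is considered.
#'
#' @param mirna,site equal-length DNA/RNA strings
#' @param model an \linkS4class{EnergyModel}
#' @return list with \code{energy}, \code{paired} (logical per miRNA
#'   position) and \code{pairType} ("GC"/"AU"/"GU"/"none")
#' @export
duplexEnergy <- function(mirna, site, model = energyModel()) {
    mirna <- .toDna(mirna); site <- .toDna(site)
    .checkAlphabet(mirna, what = "miRNA")
    .checkAlphabet(site, what = "target site")
    if (nchar(mirna) != nchar(site))
        stop("duplexEnergy requires equal lengths (bulged duplexes are ",
             "scored in scoreDuplex)")
    m <- strsplit(mirna, "")[[1]]
    t <- rev(strsplit(site, "")[[1]])
    e <- .pairEnergyChar(m, t, model)
    type <- rep("none", length(m))
    type[(m == "G" & t == "C") | (m == "C" & t == "G")] <- "GC"
    type[(m == "A" & t == "T") | (m == "T" & t == "A")] <- "AU"
    type[(m == "G" & t == "T") | (m == "T" & t == "G")] <- "GU"
    list(energy = sum(e), paired = e < 0, pairType = type)
}

#' Energy of a miRNA bound to its perfect complement
#'
#' @param mirna DNA/RNA string
#' @param model an \linkS4class{EnergyModel}
#' @return numeric energy (sum of G:C and A:U pair energies over all bases)
#' @export
perfectDuplexEnergy <- function(mirna, model = energyModel()) {
    mirna <- .toDna(mirna)
    .checkAlphabet(mirna, what = "miRNA")
    b <- strsplit(mirna, "")[[1]]
    pe <- model@pairEnergies
    sum(ifelse(b %in% c("G", "C"), pe[["GC"]], pe[["AU"]]))
}

#' Ratio of duplex energy to perfect-complement energy
#'
#' Used by the target-duplex energy rule: a candidate duplex must reach at
#' least 74 percent of the binding energy of the miRNA paired to its
#' perfect complement.
#'
#' @param duplex numeric, duplex energy (<= 0)
#' @param perfect numeric, perfect-complement energy (< 0)
#' @return \code{abs(duplex) / abs(perfect)}
#' @export
mfeRatio <- function(duplex, perfect) {
    if (perfect == 0)
        stop("perfect-complement energy is 0; ratio undefined")
    abs(duplex) / abs(perfect)
}

#' Write a structure in connect-table (CT) format
#'
#' @param x a \linkS4class{SecondaryStructure}
#' @param file output path
#' @return invisibly, the path
#' @export
writeStructureCT <- function(x, file) {
    n <- nchar(x@seq)
    b <- strsplit(x@seq, "")[[1]]
    hdr <- sprintf("%d  ENERGY = %.2f", n, x@energy)
    rows <- sprintf("%d %s %d %d %d %d", seq_len(n), b,
                    seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                    x@partner, seq_len(n))
    writeLines(c(hdr, rows), file)
    invisible(file)
}
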