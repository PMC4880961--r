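## Independent oracles used across the suite.  Deliberately naive: plain R
## recursion and character loops, sharing no code with the package paths
## they check.

.oDNA <- c("A", "C", "G", "T")
.oCOMP <- c(A = "T", C = "G", G = "C", T = "A")

oraclePairEnergy <- function(a, b, GC = -3, AU = -2, GU = -1) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(GC)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(AU)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(GU)
    Inf
}

## exhaustive minimum structure energy by unmemoised recursion over every
## non-crossing structure (either base i is unpaired, or paired to some k)
oracleMinFoldEnergy <- function(seq, GC = -3, AU = -2, GU = -1,
                                minLoop = 3) {
    b <- strsplit(seq, "")[[1]]
    rec <- function(i, j) {
        if (i >= j || j - i <= minLoop) return(0)
        best <- rec(i + 1, j)
        for (k in (i + minLoop + 1):j) {
            e <- oraclePairEnergy(b[i], b[k], GC, AU, GU)
            if (is.finite(e)) {
                cand <- e + rec(i + 1, k - 1) + rec(k + 1, j)
                if (cand < best) best <- cand
            }
        }
        best
    }
    rec(1, length(b))
}

## per-position duplex classifier, written from the rules' prose
oracleDuplex <- function(mirna, site) {
    m <- strsplit(mirna, "")[[1]]
    t <- rev(strsplit(site, "")[[1]])
    stopifnot(length(m) == length(t))
    status <- character(length(m))
    for (p in seq_along(m)) {
        if (.oCOMP[[m[p]]] == t[p]) status[p] <- "match"
        else if ((m[p] == "G" && t[p] == "T") ||
                 (m[p] == "T" && t[p] == "G")) status[p] <- "wobble"
        else status[p] <- "mismatch"
    }
    status
}

oracleRules <- function(status, energyRatio) {
    sc <- ifelse(status == "match", 0, ifelse(status == "wobble", 0.5, 1))
    n <- length(status)
    total <- sum(sc)
    adjacent <- logical(0)
    for (p in seq_len(n - 1))
        adjacent[p] <- status[p] == "mismatch" && status[p + 1] == "mismatch"
    r1 <- total < 4
    r2 <- !any(adjacent)
    r3 <- TRUE
    for (p in 2:(min(12, n) - 1))
        if (status[p] == "mismatch" && status[p + 1] == "mismatch")
            r3 <- FALSE
    r4 <- sc[10] == 0 && sc[11] == 0
    r5 <- sum(sc[1:min(12, n)]) < 2.5
    r6 <- energyRatio >= 0.74
    c(r1, r2, r3, r4, r5, r6)
}

## random mutated reverse complement: a target site for mirna carrying
## n_mut substitutions at random positions (possibly creating wobbles)
mutatedSite <- function(mirna, n_mut) {
    rc <- strsplit(as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(mirna))),
        "")[[1]]
    if (n_mut > 0) {
        pos <- sample(length(rc), n_mut)
        for (p in pos) rc[p] <- sample(setdiff(.oDNA, rc[p]), 1)
    }
    paste(rc, collapse = "")
}

randomDna <- function(len) {
    paste(sample(.oDNA, len, replace = TRUE), collapse = "")
}

## |observed - expected| within 4 binomial standard deviations
expect_within_4sigma <- function(observed, n, p) {
    sigma <- sqrt(n * p * (1 - p))
    expect_lte(abs(observed - n * p), 4 * sigma + 1e-9)
}

fixtureDir <- function() system.file("extdata", package = "sRNAkit")
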