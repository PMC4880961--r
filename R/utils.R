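## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; summary tables in the field
#' round half up, so percentages like 0.145 print as 0.15.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
roundHalfUp <- function(x, digits = 0) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

## DNA storage alphabet; U is accepted on input and converted to T.
.toDna <- function(x) chartr("Uu", "Tt", toupper(x))

## presentation layer: T -> U
.toRna <- function(x) chartr("T", "U", toupper(x))

.checkAlphabet <- function(x, allowN = FALSE, what = "sequence") {
    pat <- if (allowN) "^[ACGTN]*$" else "^[ACGT]*$"
    bad <- !grepl(pat, x)
    if (any(bad))
        stop(what, " contains invalid characters (first offender: '",
             x[which(bad)[1]], "')", call. = FALSE)
    invisible(x)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revComp <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}

## classify one opposed base pair (DNA letters, T == U)
## returns "match", "wobble" or "mismatch"
.pairClass <- function(a, b) {
    ifelse(.COMP[a] == b, "match",
           ifelse((a == "G" & b == "T") | (a == "T" & b == "G"),
                  "wobble", "mismatch"))
}

## energy of one opposed pair under a model; 0 if not pairable
.pairEnergyChar <- function(a, b, model) {
    pe <- model@pairEnergies
    ifelse((a == "G" & b == "C") | (a == "C" & b == "G"), pe[["GC"]],
    ifelse((a == "A" & b == "T") | (a == "T" & b == "A"), pe[["AU"]],
    ifelse((a == "G" & b == "T") | (a == "T" & b == "G"), pe[["GU"]], 0)))
}

## random DNA string(s) of given length(s); uses the current RNG stream
.randSeq <- function(n, len, first = NULL) {
    vapply(seq_len(n), function(i) {
        s <- sample(c("A", "C", "G", "T"), len[min(i, length(len))],
                    replace = TRUE)
        if (!is.null(first)) s[1] <- first[min(i, length(first))]
        paste(s, collapse = "")
    }, character(1))
}

## number of mismatches between x[from..from+len-1] and pattern (chars),
## vectorised over x
.prefixMismatches <- function(x, pattern, from = 1L) {
    pc <- strsplit(pattern, "")[[1]]
    len <- length(pc)
    mm <- integer(length(x))
    ok <- nchar(x) >= from + len - 1L
    mm[!ok] <- NA_integer_
    if (any(ok)) {
        sub <- substr(x[ok], from, from + len - 1L)
        m <- matrix(unlist(strsplit(sub, "")), ncol = len, byrow = TRUE)
        mm[ok] <- rowSums(m != matrix(pc, nrow = sum(ok), ncol = len,
                                      byrow = TRUE))
    }
    mm
}
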