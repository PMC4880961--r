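#' @include utils.R
NULL

.validateCtTable <- function(ct, reference_gene) {
    stopifnot(is.data.frame(ct),
              all(c("gene", "tissue", "replicate", "ct") %in%
                  colnames(ct)))
    if (any(ct$ct <= 0)) stop("Ct values must be positive")
    tissues <- unique(ct$tissue)
    refT <- unique(ct$tissue[ct$gene == reference_gene])
    missing <- setdiff(tissues, refT)
    if (length(missing))
        stop("reference gene '", reference_gene,
             "' missing for tissue(s): ", paste(missing, collapse = ", "))
    invisible(ct)
}

## per-replicate dCt values for one gene in one tissue, paired by
## replicate index with the reference gene
.dctValues <- function(ct, gene, tissue, reference_gene) {
    tg <- ct[ct$gene == gene & ct$tissue == tissue, ]
    rf <- ct[ct$gene == reference_gene & ct$tissue == tissue, ]
    m <- merge(tg[, c("replicate", "ct")], rf[, c("replicate", "ct")],
               by = "replicate", suffixes = c("_t", "_r"))
    if (nrow(m) == 0)
        stop("no paired replicates for ", gene, " in ", tissue)
    m$ct_t - m$ct_r
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt is the target Ct minus the reference-gene Ct
#' (paired by replicate index); ddCt subtracts the mean calibrator-tissue
#' dCt; the fold change is \eqn{2^{-\Delta\Delta Ct}}.  The calibrator
#' tissue's fold change is exactly 1 by construction.  The replicate SD
#' is propagated on the ddCt scale and reported as the fold range
#' \eqn{2^{-(\Delta\Delta Ct \pm SD)}}.
#'
#' @param ct data.frame with columns gene, tissue, replicate, ct
#' @param reference_gene reference (housekeeping) gene name
#' @param calibrator_tissue tissue all fold changes are normalised to
#' @param genes targets to quantify (default: every non-reference gene)
#' @return data.frame: mirna, tissue, n, dct_mean, ddct, ddct_sd, fold,
#'   fold_lo, fold_hi
#' @examples
#' ct <- data.frame(gene = c("x", "x", "ref", "ref"),
#'                  tissue = c("leaf", "fruit", "leaf", "fruit"),
#'                  replicate = 1, ct = c(24, 21, 18, 18))
#' deltaDeltaCt(ct, "ref", "leaf")   # fruit fold = 8
#' @export
deltaDeltaCt <- function(ct, reference_gene, calibrator_tissue,
                         genes = NULL) {
    .validateCtTable(ct, reference_gene)
    if (!calibrator_tissue %in% ct$tissue)
        stop("calibrator tissue '", calibrator_tissue, "' absent")
    if (is.null(genes))
        genes <- setdiff(unique(ct$gene), reference_gene)
    rows <- list()
    for (g in genes) {
        calDct <- .dctValues(ct, g, calibrator_tissue, reference_gene)
        calMean <- mean(calDct)
        for (ti in unique(ct$tissue[ct$gene == g])) {
            dct <- .dctValues(ct, g, ti, reference_gene)
            ddct <- mean(dct) - calMean
            sdd <- if (length(dct) > 1) sd(dct - calMean) else NA_real_
            rows[[length(rows) + 1L]] <- data.frame(
                mirna = g, tissue = ti, n = length(dct),
                dct_mean = mean(dct), ddct = ddct,
                ddct_sd = sdd, fold = 2^(-ddct),
                fold_lo = if (is.na(sdd)) NA_real_ else 2^(-(ddct + sdd)),
                fold_hi = if (is.na(sdd)) NA_real_ else 2^(-(ddct - sdd)),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Replicate t tests of tissue expression against the calibrator
#'
#' Two-sample two-sided Student t test (pooled variance, df = n1+n2-2) on
#' the replicate dCt values of each tissue against the calibrator tissue
#' - the scale on which qPCR noise is conventionally treated as Gaussian.
#' Stars: ** for p < 0.01, *** for p < 0.001.
#'
#' @param ct data.frame with columns gene, tissue, replicate, ct
#' @param reference_gene,calibrator_tissue as in \code{\link{deltaDeltaCt}}
#' @param genes targets to test (default: every non-reference gene)
#' @return data.frame: mirna, tissue, p_value, stars, tested (FALSE with
#'   NA p when either side has fewer than 2 replicates)
#' @export
qpcrSignificance <- function(ct, reference_gene, calibrator_tissue,
                             genes = NULL) {
    .validateCtTable(ct, reference_gene)
    if (is.null(genes))
        genes <- setdiff(unique(ct$gene), reference_gene)
    rows <- list()
    for (g in genes) {
        calDct <- .dctValues(ct, g, calibrator_tissue, reference_gene)
        for (ti in setdiff(unique(ct$tissue[ct$gene == g]),
                           calibrator_tissue)) {
            dct <- .dctValues(ct, g, ti, reference_gene)
            if (length(dct) < 2 || length(calDct) < 2) {
                rows[[length(rows) + 1L]] <- data.frame(
                    mirna = g, tissue = ti, p_value = NA_real_,
                    stars = "", tested = FALSE, stringsAsFactors = FALSE)
                next
            }
            p <- if (sd(dct) == 0 && sd(calDct) == 0) {
                if (mean(dct) == mean(calDct)) 1 else 0
            } else t.test(dct, calDct, var.equal = TRUE)$p.value
            stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else ""
            rows[[length(rows) + 1L]] <- data.frame(
                mirna = g, tissue = ti, p_value = p, stars = stars,
                tested = TRUE, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Quantify and test expression in one call
#'
#' Convenience wrapper joining \code{\link{deltaDeltaCt}} and
#' \code{\link{qpcrSignificance}}.
#'
#' @inheritParams qpcrSignificance
#' @return the \code{deltaDeltaCt} table with p_value and stars columns
#' @export
quantifyExpression <- function(ct, reference_gene, calibrator_tissue,
                               genes = NULL) {
    ex <- deltaDeltaCt(ct, reference_gene, calibrator_tissue, genes)
    sig <- qpcrSignificance(ct, reference_gene, calibrator_tissue, genes)
    out <- merge(ex, sig[, c("mirna", "tissue", "p_value", "stars")],
                 by = c("mirna", "tissue"), all.x = TRUE, sort = FALSE)
    out$stars[is.na(out$stars)] <- ""
    out[order(out$mirna, out$tissue), ]
}
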