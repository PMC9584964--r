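# Relative quantification by the comparative Ct method with propagated
# standard deviations.

#' Propagated standard deviation for a double-delta Ct
#'
#' Square root of the sum of the four squared Ct standard deviations entering
#' the double delta: gene of interest and housekeeping gene, in the
#' calibrator organ and in the organ of interest.
#'
#' @param sd_components Numeric vector of the four standard deviations, in
#'   cycles.
#' @return Propagated standard deviation in cycles.
#' @export
propagate_sd <- function(sd_components) {
  stopifnot(is.numeric(sd_components), length(sd_components) == 4L)
  if (any(sd_components < 0)) stop("negative standard deviation component")
  sqrt(sum(sd_components^2))
}

#' Relative expression by the comparative Ct method
#'
#' Per organ, delta Ct is the mean Ct of the gene of interest minus the mean
#' Ct of the housekeeping gene; the double delta subtracts the calibrator
#' organ's delta Ct, and the fold change is 2^-(double delta). The standard
#' deviation of the double delta is propagated from the four per-(gene,
#' organ) Ct standard deviations; the fold-change interval is the asymmetric
#' 2^-(double delta +/- sd) band.
#'
#' @param ct Long-format `data.frame` with columns `gene`, `organ`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @param goi Gene of interest.
#' @param hkg Housekeeping gene.
#' @param calibrator Calibrator organ (fold change 1 by construction).
#' @param pooling `"pooled"` (Ct standard deviation over all technical x
#'   biological replicates of a cell) or `"by_bio"` (standard deviation of
#'   the per-biological-replicate mean Cts).
#' @return `data.frame` with one row per organ: `organ`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`, `sd_ddct`, `fold_lo`, `fold_hi`.
#' @export
delta_delta_ct <- function(ct, goi, hkg, calibrator = "leaf",
                           pooling = c("pooled", "by_bio")) {
  pooling <- match.arg(pooling)
  stopifnot(all(c("gene", "organ", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  for (g in c(goi, hkg)) {
    if (!g %in% ct$gene) stop("gene absent from the Ct table: ", g)
  }
  if (!calibrator %in% ct$organ[ct$gene == goi] ||
      !calibrator %in% ct$organ[ct$gene == hkg]) {
    stop("missing calibrator data: ", calibrator)
  }
  cell <- function(gene, organ) ct[ct$gene == gene & ct$organ == organ, ]
  cell_stats <- function(gene, organ) {
    d <- cell(gene, organ)
    if (nrow(d) == 0L) stop("no Ct data for ", gene, " in ", organ)
    if (pooling == "by_bio" && "bio_rep" %in% names(d)) {
      v <- tapply(d$ct, d$bio_rep, mean)
    } else {
      v <- d$ct
    }
    s <- if (length(v) > 1L) stats::sd(v) else 0
    c(mean = mean(v), sd = s)
  }
  organs <- unique(ct$organ[ct$gene == goi])
  cal_goi <- cell_stats(goi, calibrator)
  cal_hkg <- cell_stats(hkg, calibrator)
  dct_cal <- cal_goi[["mean"]] - cal_hkg[["mean"]]
  rows <- lapply(organs, function(o) {
    s_goi <- cell_stats(goi, o)
    s_hkg <- cell_stats(hkg, o)
    dct <- s_goi[["mean"]] - s_hkg[["mean"]]
    ddct <- dct - dct_cal
    sdd <- propagate_sd(c(cal_goi[["sd"]], cal_hkg[["sd"]],
                          s_goi[["sd"]], s_hkg[["sd"]]))
    data.frame(
      organ = o, delta_ct = dct, delta_delta_ct = ddct,
      fold_change = 2^(-ddct), sd_ddct = sdd,
      fold_lo = 2^(-(ddct + sdd)), fold_hi = 2^(-(ddct - sdd))
    )
  })
  out <- do.call(rbind, rows)
  out$delta_delta_ct[out$organ == calibrator] <- 0
  out$fold_change[out$organ == calibrator] <- 1
  rownames(out) <- NULL
  out
}

#' Read a long-format Ct table
#' @param path Tab-separated file with header `gene`, `organ`, `bio_rep`,
#'   `tech_rep`, `ct`.
#' @return `data.frame`.
#' @export
read_ct_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
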