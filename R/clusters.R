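connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6" = g[nz == 1, , drop = FALSE],
         "18" = g[nz >= 1 & nz <= 2, , drop = FALSE],
         "26" = g[nz >= 1, , drop = FALSE],
         stop("connectivity must be 6, 18 or 26"))
}

# label connected components among the given 0-based linear voxel indices
label_components <- function(lin0, dims, connectivity) {
  if (!length(lin0)) return(integer(0))
  off <- connectivity_offsets(connectivity)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  x <- lin0 %% nx; y <- (lin0 %/% nx) %% ny; z <- lin0 %/% (nx * ny)
  labels <- integer(length(lin0))
  cur <- 0L
  lookup <- new.env(hash = TRUE, size = length(lin0))
  for (i in seq_along(lin0)) assign(as.character(lin0[i]), i, envir = lookup)
  for (i in seq_along(lin0)) {
    if (labels[i] > 0) next
    cur <- cur + 1L
    queue <- i
    labels[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nxs <- x[v] + off[, 1]; nys <- y[v] + off[, 2]; nzs <- z[v] + off[, 3]
      ok <- nxs >= 0 & nxs < nx & nys >= 0 & nys < ny & nzs >= 0 & nzs < nz
      cand <- nxs[ok] + nx * (nys[ok] + ny * nzs[ok])
      for (cc in cand) {
        j <- mget(as.character(cc), envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && labels[j] == 0) {
          labels[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

max_cluster_extent <- function(stat_arr, threshold, connectivity) {
  supra <- which(is.finite(stat_arr) & stat_arr > threshold) - 1L
  if (!length(supra)) return(0)
  labels <- label_components(supra, dim(stat_arr), connectivity)
  max(tabulate(labels))
}

#' Supra-threshold clusters of a statistic map
#'
#' Connected components of `{t > threshold}` under 6-, 18- (default) or
#' 26-neighbor connectivity. Rows are sorted by peak statistic, descending;
#' extent is the cluster size KE in voxels.
#'
#' @param statmap A `stat_map` (3-D `data`).
#' @param threshold Cluster-forming threshold on the statistic.
#' @param connectivity 6, 18 or 26.
#' @param geometry Optional [acq_geometry()]; if given, peak world mm
#'   coordinates are reported via its affine.
#' @return data.frame: `cluster_id`, `peak_x`, `peak_y`, `peak_z` (1-based
#'   voxel indices), `x_mm`, `y_mm`, `z_mm`, `peak_stat`, `extent`.
#' @export
extract_clusters <- function(statmap, threshold, connectivity = 18L,
                             geometry = NULL) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  arr <- statmap$data
  stopifnot(length(dim(arr)) == 3)
  supra <- which(is.finite(arr) & arr > threshold) - 1L
  empty <- data.frame(cluster_id = integer(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      peak_stat = numeric(0), extent = integer(0))
  if (!length(supra)) return(empty)
  labels <- label_components(supra, dim(arr), connectivity)
  vals <- arr[supra + 1L]
  rows <- lapply(seq_len(max(labels)), function(l) {
    members <- supra[labels == l]
    v <- vals[labels == l]
    peak <- members[which.max(v)]
    d <- dim(arr)
    px <- peak %% d[1]; py <- (peak %/% d[1]) %% d[2]; pz <- peak %/% (d[1] * d[2])
    mm <- c(NA_real_, NA_real_, NA_real_)
    if (!is.null(geometry)) {
      mm <- (geometry_affine(geometry) %*% c(px, py, pz, 1))[1:3]
    }
    data.frame(cluster_id = l, peak_x = px + 1L, peak_y = py + 1L,
               peak_z = pz + 1L, x_mm = mm[1], y_mm = mm[2], z_mm = mm[3],
               peak_stat = max(v), extent = length(members))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$peak_stat), , drop = FALSE]
  tab$cluster_id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Write a cluster table as TSV
#'
#' Columns `label`, `x_mm`, `y_mm`, `z_mm`, `t_value`, `KE`, `p_corrected`
#' mirror the conventional cluster-report layout (peak coordinates, peak
#' statistic, cluster extent, corrected p).
#'
#' @param tab Cluster table from [extract_clusters()] (with or without a
#'   `p_corrected` column).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_table <- function(tab, path) {
  out <- data.frame(label = tab$cluster_id,
                    x_mm = tab$x_mm, y_mm = tab$y_mm, z_mm = tab$z_mm,
                    t_value = tab$peak_stat, KE = tab$extent,
                    p_corrected = if ("p_corrected" %in% names(tab))
                      tab$p_corrected else NA_real_)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
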