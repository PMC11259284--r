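#' Export / import a network snapshot
#'
#' The snapshot is a TSV edge list (pre_index, post_index, weight,
#' birth_iteration; 1-based indices, weights at full precision) plus a JSON
#' sidecar holding the geometry (positions, m, L, jitter bound), the
#' per-neuron leak conductances and an optional parameter echo. The round
#' trip is lossless for weights and positions.
#'
#' @param conn a \code{plast_conn}
#' @param geometry a \code{plast_geometry}
#' @param g_leak per-neuron leak conductances
#' @param path base path; writes \code{<path>.edges.tsv} and
#'   \code{<path>.json}
#' @param extra optional named list echoed into the sidecar (parameters,
#'   seeds)
#' @return invisibly, the two file paths
#' @export
write_network <- function(conn, geometry, g_leak, path, extra = list()) {
  stopifnot(inherits(conn, "plast_conn"), inherits(geometry, "plast_geometry"))
  edges <- which(conn$A == 1L, arr.ind = TRUE)
  df <- data.frame(pre_index = edges[, 2], post_index = edges[, 1],
                   weight = conn$W[edges],
                   birth_iteration = conn$birth[edges])
  tsv <- paste0(path, ".edges.tsv")
  json <- paste0(path, ".json")
  write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(m = geometry$m, L = geometry$L,
                 jitter_scale = geometry$jitter_scale,
                 x = geometry$positions[, 1], y = geometry$positions[, 2],
                 g_leak = g_leak), extra)
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(edges = tsv, sidecar = json))
}

#' @rdname write_network
#' @param path base path used at write time
#' @return \code{read_network} returns a list with \code{conn},
#'   \code{geometry}, \code{g_leak} and \code{extra}
#' @export
read_network <- function(path) {
  df <- read.table(paste0(path, ".edges.tsv"), header = TRUE, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geometry <- list(m = side$m, L = side$L, h = side$L / (side$m - 1),
                   N = side$m^2, jitter_scale = side$jitter_scale,
                   positions = cbind(x = side$x, y = side$y))
  geometry$distance <- as.matrix(dist(geometry$positions))
  dimnames(geometry$distance) <- NULL
  class(geometry) <- "plast_geometry"
  conn <- empty_connectivity(geometry$N)
  if (nrow(df)) {
    idx <- cbind(df$post_index, df$pre_index)
    conn$A[idx] <- 1L
    conn$W[idx] <- df$weight
    conn$birth[idx] <- as.integer(df$birth_iteration)
  }
  known <- c("m", "L", "jitter_scale", "x", "y", "g_leak")
  list(conn = conn, geometry = geometry, g_leak = side$g_leak,
       extra = side[setdiff(names(side), known)])
}

#' Write a spike raster as two-column TSV
#'
#' @param raster data.frame with columns \code{time}, \code{neuron}
#' @param path file path
#' @export
write_raster <- function(raster, path) {
  write.table(raster[, c("time", "neuron")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
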