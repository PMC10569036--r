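#' Save / load a trained fragment model
#'
#' A model is stored as a directory: `weights.bin` (flattened layer weights
#' and biases as little-endian doubles) plus `model.json` (layer dimensions,
#' fragment catalog, input column names, input scaling statistics and
#' training configuration). The JSON sidecar is sufficient to rebuild the
#' object shape; the binary file carries only the numbers.
#'
#' @param model A trained `fragment_net`.
#' @param dir Directory to create/write.
#'
#' @return Invisibly, `dir`.
#' @export
save_fragment_net <- function(model, dir) {
  stopifnot(inherits(model, "fragment_net"), isTRUE(model$trained))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- unlist(c(lapply(model$net$w, as.numeric),
                   lapply(model$net$b, as.numeric)))
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  writeBin(flat, con, size = 8, endian = "little")
  sidecar <- list(
    dims = model$net$dims, n_relu = model$net$n_relu,
    dropout = model$net$dropout, catalog = model$catalog,
    input_cols = model$input_cols,
    scaling = list(mean = unname(model$scaling$mean),
                   sd = unname(model$scaling$sd)),
    config = model$config
  )
  jsonlite::write_json(sidecar, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_fragment_net
#' @export
load_fragment_net <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "model.json"),
                                 simplifyVector = TRUE)
  dims <- as.numeric(sidecar$dims)
  n_layers <- length(dims) - 1L
  n_vals <- sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1])
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  flat <- readBin(con, "double", n = n_vals, size = 8, endian = "little")
  w <- vector("list", n_layers)
  b <- vector("list", n_layers)
  pos <- 0L
  for (i in seq_len(n_layers)) {
    len <- dims[i] * dims[i + 1]
    w[[i]] <- matrix(flat[pos + seq_len(len)], nrow = dims[i])
    pos <- pos + len
  }
  for (i in seq_len(n_layers)) {
    len <- dims[i + 1]
    b[[i]] <- flat[pos + seq_len(len)]
    pos <- pos + len
  }
  scaling <- list(mean = setNames(as.numeric(sidecar$scaling$mean),
                                  sidecar$input_cols),
                  sd = setNames(as.numeric(sidecar$scaling$sd),
                                sidecar$input_cols))
  structure(
    list(net = list(w = w, b = b, dims = dims,
                    n_relu = as.integer(sidecar$n_relu),
                    dropout = sidecar$dropout),
         catalog = sidecar$catalog, input_cols = sidecar$input_cols,
         scaling = scaling, trained = TRUE, report = NULL,
         config = sidecar$config),
    class = "fragment_net"
  )
}
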