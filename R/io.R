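#' Load a parameter configuration
#'
#' Reads a flat YAML or JSON mapping of parameter names (the argument
#' names of [fear_params()]) to values. Missing keys take the default
#' values; unknown keys are an error; the result is validated.
#' An empty file yields the full default parameter set.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `fear_params` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(fear_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(fear_params, cfg)
}

#' Write a session trace to CSV
#'
#' @param trace A trace data frame from [run_session()] /
#'   [session_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a network snapshot
#'
#' JSON snapshot of the full synaptic state: anatomical afferents,
#' potentiated entorhinal synapses (as per-cell attribute sets --
#' weights are implied equal at 1/set size), potentiated recurrent
#' pairs, output synapses, representations and amygdala weights.
#' `read_net(write_net(net))` reproduces the network exactly.
#'
#' @param net A `hippocampal_net`.
#' @param path File path.
#' @return `write_net` returns `path` invisibly; `read_net` the
#'   restored network.
#' @export
write_net <- function(net, path) {
  rec_idx <- Matrix::which(net$rec, arr.ind = TRUE)
  obj <- list(
    params = unclass(net$p), seed = net$seed,
    dg_aff = apply(net$dg_aff, 1L, identity, simplify = FALSE),
    ca3_aff = apply(net$ca3_aff, 1L, identity, simplify = FALSE),
    dg_pot = net$dg_pot, ca3_pot = net$ca3_pot,
    rec_pairs = unname(apply(rec_idx, 1L, identity, simplify = FALSE)),
    out_pot = net$out_pot,
    reps = lapply(unname(net$reps), function(r)
      list(id = r$id, cells = r$cells, created_at_Zcur = r$created_at_Zcur,
           context_id = r$context_id)),
    amyg_w = net$amyg_w
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_net
#' @export
read_net <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  p <- do.call(fear_params, obj$params)
  net <- new.env(parent = emptyenv())
  net$p <- p
  net$seed <- as.integer(obj$seed)
  to_row <- function(x) as.integer(unlist(x))
  net$dg_aff <- do.call(rbind, lapply(obj$dg_aff, to_row))
  net$ca3_aff <- do.call(rbind, lapply(obj$ca3_aff, to_row))
  as_pot <- function(lst) lapply(lst, function(x)
    if (is.null(x) || !length(x)) NULL else as.integer(unlist(x)))
  net$dg_pot <- as_pot(obj$dg_pot)
  net$ca3_pot <- as_pot(obj$ca3_pot)
  net$out_pot <- as_pot(obj$out_pot)
  if (length(obj$rec_pairs)) {
    ij <- do.call(rbind, lapply(obj$rec_pairs, to_row))
    net$rec <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2],
                                    dims = c(p$N_hipp, p$N_hipp))
  } else {
    net$rec <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                    dims = c(p$N_hipp, p$N_hipp))
  }
  net$reps <- list()
  for (r in obj$reps) {
    rec <- list(id = r$id, cells = as.integer(unlist(r$cells)),
                created_at_Zcur = r$created_at_Zcur,
                context_id = r$context_id)
    net$reps[[rec$id]] <- rec
  }
  net$amyg_w <- as.numeric(unlist(obj$amyg_w))
  class(net) <- "hippocampal_net"
  net
}

#' Write experiment outputs with a reproducibility manifest
#'
#' Writes each named data frame in `results` as `<name>.csv` in `dir`
#' and finishes with `manifest.json` recording the configuration, base
#' seed and an md5 checksum of every file, so a run can be verified and
#' reproduced.
#'
#' @param results Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param p The `fear_params` used.
#' @param seed The base seed used.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(results, dir, p, seed) {
  stopifnot(length(results) > 0, !is.null(names(results)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(results)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ctxfear")),
    params = unclass(p),
    seed = seed,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
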