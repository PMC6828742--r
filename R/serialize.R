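# JSON (de)serialization of fitted ensembles. Doubles are written at full
# precision so a round trip reproduces predictions bit-exactly; leaf
# thresholds (never read during prediction) are stored as 0 to keep the
# file NA-free.

#' Serialize a fitted ensemble to JSON
#'
#' @param model a `bite_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [read_bite_json()]
#' @export
write_bite_json <- function(model, path) {
  stopifnot(inherits(model, "bite_ensemble"))
  cfg <- model$config
  trees <- lapply(model$trees, function(tr) {
    thr <- tr$threshold
    thr[is.na(thr)] <- 0
    list(var = tr$var, threshold = thr, left = tr$left, right = tr$right,
         value = tr$value, nsamp = tr$nsamp)
  })
  obj <- list(
    format = "netbite-ensemble", version = 1L,
    config = list(n_tree = cfg$n_tree, mtry = cfg$mtry, tps = cfg$tps,
                  bootstrap = cfg$bootstrap, seed = cfg$seed),
    gene_ids = model$gene_ids,
    n_train = model$n_train,
    bias = as.numeric(model$bias),
    trees = trees
  )
  # I(17) = 17 *significant* digits: doubles survive the round trip
  # bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load an ensemble serialized with [write_bite_json()]
#'
#' @param path JSON file written by [write_bite_json()].
#' @return A `bite_ensemble` whose predictions match the original
#'   bit-exactly (bootstrap indices are not stored and come back `NULL`).
#' @export
read_bite_json <- function(path) {
  if (!file.exists(path)) stop_user("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "netbite-ensemble"))
    stop_user(path, " is not a serialized netbite ensemble")
  cfg <- bite_config(n_tree = obj$config$n_tree, mtry = obj$config$mtry,
                     tps = obj$config$tps, bootstrap = obj$config$bootstrap,
                     seed = obj$config$seed)
  mk <- function(tr) {
    out <- list(var = as.integer(tr$var), threshold = as.numeric(tr$threshold),
                left = as.integer(tr$left), right = as.integer(tr$right),
                value = as.numeric(tr$value), nsamp = as.integer(tr$nsamp))
    class(out) <- "bite_tree"
    out
  }
  trees <- lapply(obj$trees, mk)
  structure(list(trees = trees, config = cfg,
                 gene_ids = as.character(obj$gene_ids),
                 n_train = as.integer(obj$n_train),
                 bias = as.numeric(obj$bias), bootstrap_indices = NULL),
            class = "bite_ensemble")
}
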