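# File readers, flat run-configuration files and the command-line
# interface. The CLI is a thin layer over the package functions; exit
# codes are 0 (ok), 1 (user error: bad flags, malformed or missing
# inputs) and 2 (internal error).

#' Read an expression matrix from TSV/CSV
#'
#' Expects a sample-id column (first column) and genes as the remaining
#' columns; `orientation = "genes"` transposes a genes-as-rows export.
#' The delimiter is inferred from the extension (`.csv` vs anything
#' else).
#'
#' @param path input file.
#' @param orientation `"samples"` (rows are samples, default) or
#'   `"genes"`.
#' @return Numeric matrix, samples x genes.
#' @export
read_expression <- function(path, orientation = c("samples", "genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_user("file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                    check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(tab)
  if (!is.numeric(X)) stop_user("non-numeric expression values in ", path)
  if (orientation == "genes") X <- t(X)
  if (anyNA(X)) stop_user("missing expression values in ", path)
  X
}

#' @rdname read_expression
#' @param x matrix to write.
#' @export
write_expression <- function(x, path) {
  tab <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample response vector
#'
#' Two-column TSV `sample_id <tab> value` (header optional, one-column
#' files are taken in order).
#'
#' @param path input file.
#' @return Named numeric vector.
#' @export
read_response <- function(path) {
  if (!file.exists(path)) stop_user("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[length(first)])))
  tab <- read.table(path, header = has_header, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) == 1) return(as.numeric(tab[[1]]))
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Read drug-target gene lists
#'
#' JSON files may hold either an array of gene ids or an object mapping
#' drug names to arrays; TSV files either a single gene-id column or
#' `drug <tab> gene` pairs.
#'
#' @param path input file (`.json` or TSV).
#' @return Character vector of gene ids, or a named list of them when
#'   the file maps several drugs.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop_user("file not found: ", path)
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(obj)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  if (all(lengths(parts) == 1)) return(unlist(parts))
  drugs <- vapply(parts, `[[`, "", 1)
  split(vapply(parts, `[[`, "", 2), drugs)
}

#' Read a flat run-configuration file
#'
#' INI-style `key = value` lines; `#` comments and `[section]` headers
#' are ignored. Values are typed: numbers become numeric, `true/false`
#' logical, comma-separated values vectors.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_user("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop_user("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(tolower(vals) %in% c("true", "false"))) tolower(vals) == "true"
      else if (length(vals) > 1) vals else val
  }
  out
}

log_kv <- function(cmd, ..., .t0 = NULL) {
  kv <- list(...)
  if (!is.null(.t0))
    kv$runtime_s <- round((proc.time() - .t0)[["elapsed"]], 3)
  message(sprintf("[netbite:%s] %s", cmd,
                  paste(names(kv), vapply(kv, function(v)
                    paste(format(v), collapse = ","), ""),
                    sep = "=", collapse = " ")))
}

default_config <- function(config) {
  defaults <- list(n_tree = 500, mtry = "n_targets", tps = 1,
                   high_weight = 1, epsilon = 1e-5, bootstrap = TRUE,
                   alpha = 0.7, tolerance = 1e-6, k = "auto", repeats = 10,
                   seed = 1, orientation = "samples")
  modifyList(defaults, config)
}

resolve_mtry_policy <- function(mtry, n_targets, n_genes) {
  if (identical(mtry, "n_targets")) return(max(1L, n_targets))
  if (identical(mtry, "all")) return(n_genes)
  as.integer(mtry)
}

#' Pipeline commands
#'
#' Programmatic equivalents of the CLI subcommands; each takes a flat
#' configuration list (see [read_run_config()]) and writes its outputs
#' under the configured paths. `netbite_cli()` dispatches a character
#' argument vector (as from `commandArgs(trailingOnly = TRUE)`) to these
#' and returns the process exit status instead of quitting, which keeps
#' it testable in-session; the installed script `cli/netbite.R` forwards
#' that status to `quit()`.
#'
#' @param config named list; recognized keys mirror the CLI flags
#'   (`expression`, `response`, `targets`, `ppi`, `out`/`out_dir`,
#'   `n_tree`, `mtry`, `tps`, `high_weight`, `epsilon`, `alpha`,
#'   `tolerance`, `k`, `repeats`, `seed`, ...). Defaults follow the
#'   drug-sensitivity protocol: `n_tree 500`, `tps 1`, `alpha 0.7`,
#'   `epsilon 1e-5`, `repeats 10`, `mtry "n_targets"`.
#' @return The main output path, invisibly.
#' @export
cmd_propagate <- function(config) {
  t0 <- proc.time()
  config <- default_config(config)
  for (key in c("ppi", "targets", "out"))
    if (is.null(config[[key]])) stop_user("config key '", key, "' is required")
  if (!(config$alpha > 0 && config$alpha < 1))
    stop_user("alpha must lie strictly in (0, 1)")
  graph <- read_string_graph(config$ppi, mapping = config$mapping)
  targets <- read_targets(config$targets)
  if (is.list(targets)) targets <- unlist(targets, use.names = FALSE)
  universe <- if (!is.null(config$expression))
    colnames(read_expression(config$expression, config$orientation))
  else graph$nodes
  w0 <- initial_weights(targets, universe, config$high_weight, config$epsilon)
  ws <- propagate_weights(w0, graph,
                          propagation_config(alpha = config$alpha,
                                             tol = config$tolerance))
  write_weights_tsv(ws, config$out)
  log_kv("propagate", universe = length(universe), targets = length(targets),
         skipped = attr(w0, "skipped"), alpha = config$alpha,
         iterations = attr(ws, "iterations"), out = config$out, .t0 = t0)
  invisible(config$out)
}

#' @rdname cmd_propagate
#' @export
cmd_fit_predict <- function(config) {
  t0 <- proc.time()
  config <- default_config(config)
  for (key in c("expression", "response", "out_dir"))
    if (is.null(config[[key]])) stop_user("config key '", key, "' is required")
  X <- read_expression(config$expression, config$orientation)
  y <- read_response(config$response)
  if (length(y) != nrow(X)) stop_user("response length does not match samples")
  bias <- NULL
  n_targets <- 0L
  if (!is.null(config$weights)) {
    bias <- read_weights_tsv(config$weights)
    n_targets <- sum(bias == max(bias))
  } else if (!is.null(config$targets)) {
    targets <- read_targets(config$targets)
    if (is.list(targets)) targets <- unlist(targets, use.names = FALSE)
    bias <- initial_weights(targets, colnames(X), config$high_weight,
                            config$epsilon)
    n_targets <- length(attr(bias, "targets"))
  }
  mtry <- resolve_mtry_policy(config$mtry, n_targets, ncol(X))
  fit <- fit_bite(X, as.numeric(scale_ic50(y)),
                  bite_config(n_tree = config$n_tree, mtry = mtry,
                              tps = config$tps, bias = bias,
                              bootstrap = config$bootstrap,
                              seed = config$seed))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pred_path <- file.path(config$out_dir, "predictions.tsv")
  model_path <- file.path(config$out_dir, "model.json")
  preds <- predict(fit, X)
  # full precision so the table matches the serialized model exactly
  write.table(data.frame(sample_id = rownames(X),
                         prediction = sprintf("%.17g", preds)),
              pred_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_bite_json(fit, model_path)
  log_kv("fit-predict", samples = nrow(X), genes = ncol(X), mtry = mtry,
         n_tree = config$n_tree, seed = config$seed, out = pred_path, .t0 = t0)
  invisible(pred_path)
}

#' @rdname cmd_propagate
#' @export
cmd_benchmark <- function(config) {
  t0 <- proc.time()
  config <- default_config(config)
  config <- modifyList(list(n_samples = 200, n_genes = 200, w = 0.6,
                            n_tree_grid = c(10, 100), mtry_grid = c(2, 200)),
                       config)
  if (is.null(config$out)) stop_user("config key 'out' is required")
  bm <- make_benchmark(config$n_samples, config$n_genes, seed = config$seed)
  w0 <- initial_weights(bm$targets, colnames(bm$expression), config$w,
                        config$epsilon)
  rows <- list()
  for (nt in config$n_tree_grid) for (mt in config$mtry_grid) {
    for (arm in c("BiTE", "RF")) {
      rep_am <- crossval_rho(
        bm$expression, as.numeric(bm$ic50_scaled),
        bite_model(n_tree = nt, mtry = min(mt, config$n_genes),
                   tps = config$tps,
                   bias = if (arm == "BiTE") w0, label = arm),
        k = config$k, repeats = config$repeats, seed = config$seed)
      rows[[length(rows) + 1L]] <-
        data.frame(model = arm, n_tree = nt, mtry = mt,
                   mean_rho = rep_am$mean_rho, sd_rho = sd(rep_am$rho))
    }
  }
  out <- do.call(rbind, rows)
  write.table(out, config$out, sep = "\t", quote = FALSE, row.names = FALSE)
  log_kv("benchmark", n_samples = config$n_samples, n_genes = config$n_genes,
         rows = nrow(out), seed = config$seed, out = config$out, .t0 = t0)
  invisible(config$out)
}

#' @rdname cmd_propagate
#' @export
cmd_compare <- function(config) {
  t0 <- proc.time()
  config <- default_config(config)
  for (key in c("expression", "response", "out_dir"))
    if (is.null(config[[key]])) stop_user("config key '", key, "' is required")
  X <- read_expression(config$expression, config$orientation)
  y <- read_response(config$response)
  bias <- if (!is.null(config$weights)) read_weights_tsv(config$weights)
  else {
    targets <- read_targets(config$targets)
    if (is.list(targets)) targets <- unlist(targets, use.names = FALSE)
    initial_weights(targets, colnames(X), config$high_weight, config$epsilon)
  }
  n_targets <- if (!is.null(attr(bias, "targets")))
    length(attr(bias, "targets")) else sum(bias == max(bias))
  mtry <- resolve_mtry_policy(config$mtry, n_targets, ncol(X))
  grid <- as.integer(config$n_tree_grid %||% config$n_tree)
  tab <- compare_models(X, as.numeric(scale_ic50(y)), bias,
                        n_tree_grid = grid, mtry = mtry, tps = config$tps,
                        k = config$k, repeats = config$repeats,
                        seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(config$out_dir, "compare.tsv")
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  reports <- attr(tab, "reports")
  sidecar <- list(config = config[c("n_tree_grid", "mtry", "tps", "k",
                                    "repeats", "seed")],
                  mtry_resolved = mtry,
                  fold_hash = lapply(reports, function(r) r$biased$fold_hash),
                  rho_biased = lapply(reports, function(r) r$biased$rho),
                  rho_rf = lapply(reports, function(r) r$rf$rho))
  jsonlite::write_json(sidecar, file.path(config$out_dir, "compare.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  log_kv("compare", rows = nrow(tab), mtry = mtry, seed = config$seed,
         out = tsv, .t0 = t0)
  invisible(tsv)
}

#' @rdname cmd_propagate
#' @export
cmd_make_fixtures <- function(config) {
  t0 <- proc.time()
  config <- default_config(config)
  config <- modifyList(list(n_samples = 200, n_genes = 200,
                            effectors_per_target = 3,
                            background_density = 0.02), config)
  if (is.null(config$out_dir)) stop_user("config key 'out_dir' is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  bm <- make_benchmark(config$n_samples, config$n_genes, seed = config$seed)
  fixture <- make_ppi_fixture(colnames(bm$expression), bm$targets,
                              config$effectors_per_target,
                              config$background_density, seed = config$seed)
  paths <- c(expression = file.path(config$out_dir, "expression.tsv"),
             response = file.path(config$out_dir, "response.tsv"),
             targets = file.path(config$out_dir, "targets.tsv"),
             ppi = file.path(config$out_dir, "ppi.tsv"))
  write_expression(bm$expression, paths["expression"])
  write.table(data.frame(sample_id = rownames(bm$expression),
                         ic50 = bm$ic50),
              paths["response"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bm$targets, paths["targets"])
  write_string_edges(fixture, paths["ppi"])
  log_kv("make-fixtures", out_dir = config$out_dir, seed = config$seed,
         targets = paste(bm$targets, collapse = ","), .t0 = t0)
  invisible(config$out_dir)
}

cli_commands <- c("propagate", "fit-predict", "benchmark", "compare",
                  "make-fixtures")

#' @rdname cmd_propagate
#' @param args character vector of command-line arguments: a subcommand
#'   (`propagate`, `fit-predict`, `benchmark`, `compare`,
#'   `make-fixtures`) followed by `--key value` flags; `--config FILE`
#'   loads a [read_run_config()] file first and explicit flags override
#'   it.
#' @export
netbite_cli <- function(args) {
  if (length(args) == 0 || !(args[1] %in% cli_commands)) {
    message("usage: netbite <", paste(cli_commands, collapse = "|"),
            "> [--config FILE] [--key value ...]")
    return(1L)
  }
  cmd <- args[1]
  status <- tryCatch({
    config <- parse_cli_flags(args[-1])
    fun <- switch(cmd,
                  "propagate" = cmd_propagate,
                  "fit-predict" = cmd_fit_predict,
                  "benchmark" = cmd_benchmark,
                  "compare" = cmd_compare,
                  "make-fixtures" = cmd_make_fixtures)
    fun(config)
    0L
  }, netbite_user_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  }, error = function(e) {
    message("internal error: ", conditionMessage(e))
    2L
  })
  status
}

# --key value pairs (plus --config FILE merged first; flags win)
parse_cli_flags <- function(args) {
  config <- list()
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!grepl("^--", a)) stop_user("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i + 1L > length(args)) stop_user("flag --", key, " needs a value")
    val <- args[i + 1L]
    vals <- strsplit(val, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    parsed <- if (!anyNA(num)) num
      else if (all(tolower(vals) %in% c("true", "false"))) tolower(vals) == "true"
      else if (length(vals) > 1) vals else val
    if (key == "config") config <- read_run_config(val)
    else flags[[gsub("-", "_", key)]] <- parsed
    i <- i + 2L
  }
  modifyList(config, flags)
}
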