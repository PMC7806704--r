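# CSV dialect: comma-separated, UTF-8, header row, "." decimal. Numeric
# values are written with %.17g so write -> read round trips are exact;
# fields are quoted only when they contain a comma, quote or newline, so
# identical objects always serialize to byte-identical files.

csv_quote <- function(x) {
  x <- as.character(x)
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

fmt_num <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  full <- sprintf("%.17g", x[ok])
  clean <- sprintf("%.15g", x[ok])  # shorter form when it loses nothing
  exact <- as.numeric(clean) == x[ok]
  full[exact] <- clean[exact]
  out[ok] <- full
  out
}

write_table_lines <- function(fields_list, path, sep = ",") {
  lines <- vapply(fields_list, function(f) paste(csv_quote(f), collapse = sep),
                  character(1))
  con <- file(path, "wb")  # fixed newline across platforms
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

read_table_checked <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

check_numeric_column <- function(df, col, path, min = -Inf) {
  v <- df[[col]]
  if (is.character(v)) v <- suppressWarnings(as.numeric(v))
  bad <- which(!is.finite(v))
  if (length(bad))
    stop("file ", path, ", column '", col, "', line ", bad[1] + 1L,
         ": non-numeric or non-finite value '", df[[col]][bad[1]], "'")
  low <- which(v < min)
  if (length(low))
    stop("file ", path, ", column '", col, "', line ", low[1] + 1L,
         ": value ", v[low[1]], " below ", min)
  v
}

#' Write a combination design to CSV
#'
#' Columns: \code{combination_id}, \code{replicate}, then one dose column
#' per probiotic. Doses are written in full precision so a write/read
#' round trip reproduces the object exactly.
#'
#' @param design a \code{\link{combination_design}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_design <- function(design, path) {
  ids <- probiotic_ids(design)
  rows <- c(list(c("combination_id", "replicate", ids)),
            lapply(seq_len(nrow(design)), function(i)
              c(design$combination_id[i], as.character(design$replicate[i]),
                fmt_num(unlist(as.data.frame(design)[i, ids])))))
  write_table_lines(rows, path)
  invisible(path)
}

#' Read a combination design from CSV
#'
#' @param path CSV written by \code{\link{write_design}} (columns
#'   \code{combination_id}, \code{replicate}, one column per probiotic).
#' @return a \code{\link{combination_design}}.
#' @export
read_design <- function(path) {
  df <- read_table_checked(path)
  need <- c("combination_id", "replicate")
  if (!all(need %in% names(df)))
    stop("file ", path, ": malformed header, expected columns ",
         paste(need, collapse = ", "), " then probiotic dose columns")
  ids <- setdiff(names(df), need)
  if (!length(ids)) stop("file ", path, ": no probiotic dose columns")
  doses <- sapply(ids, function(p)
    check_numeric_column(df, p, path, min = 0))
  doses <- matrix(doses, ncol = length(ids), dimnames = list(NULL, ids))
  combination_design(df$combination_id,
                     check_numeric_column(df, "replicate", path, min = 1),
                     doses)
}

#' Write a metabolite panel to CSV
#' @param panel a \code{\link{metabolite_panel}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_panel <- function(panel, path) {
  ids <- metabolite_ids(panel)
  rows <- c(list(c("combination_id", "replicate", ids)),
            lapply(seq_len(nrow(panel)), function(i)
              c(panel$combination_id[i], as.character(panel$replicate[i]),
                fmt_num(unlist(as.data.frame(panel)[i, ids])))))
  write_table_lines(rows, path)
  invisible(path)
}

#' Read a metabolite panel from CSV, validating alignment with a design
#'
#' @param path CSV with columns \code{combination_id}, \code{replicate},
#'   one column per metabolite.
#' @param design the \code{\link{combination_design}} the panel rows must
#'   align with (same (combination, replicate) keys in the same order).
#' @return a \code{\link{metabolite_panel}}.
#' @export
read_panel <- function(path, design) {
  df <- read_table_checked(path)
  need <- c("combination_id", "replicate")
  if (!all(need %in% names(df)))
    stop("file ", path, ": malformed header, expected columns ",
         paste(need, collapse = ", "), " then metabolite columns")
  ids <- setdiff(names(df), need)
  if (!length(ids)) stop("file ", path, ": no metabolite columns")
  vals <- sapply(ids, function(m)
    check_numeric_column(df, m, path, min = 0))
  vals <- matrix(vals, ncol = length(ids), dimnames = list(NULL, ids))
  tmp <- data.frame(combination_id = as.character(df$combination_id),
                    replicate = as.integer(df$replicate),
                    stringsAsFactors = FALSE)
  check_alignment(design, tmp)
  metabolite_panel(design, vals)
}

#' Write a synergy report as long-format TSV
#'
#' One row per retained term (\code{masked = FALSE}) plus one row per
#' masked metabolite (\code{masked = TRUE}, empty term fields).
#'
#' @param report a \code{"synergy_report"}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_report <- function(report, path) {
  header <- c("metabolite", "term_label", "degree", "coefficient",
              "percentage", "masked")
  tt <- report$terms
  rows <- list(header)
  for (m in report$metabolite_ids) {
    sel <- which(tt$metabolite == m)
    if (length(sel)) {
      for (i in sel)
        rows[[length(rows) + 1L]] <- c(m, tt$term_label[i],
                                       as.character(tt$degree[i]),
                                       fmt_num(tt$coefficient[i]),
                                       fmt_num(tt$percentage[i]), "FALSE")
    } else {
      rows[[length(rows) + 1L]] <- c(m, "", "", "", "", "TRUE")
    }
  }
  write_table_lines(rows, path, sep = "\t")
  invisible(path)
}

#' Read a synergy report written by \code{\link{write_report}}
#' @param path TSV path.
#' @return a \code{"synergy_report"} (reference levels are not stored in
#'   the TSV and come back as \code{NA}).
#' @export
read_report <- function(path) {
  df <- read_table_checked(path, sep = "\t")
  need <- c("metabolite", "term_label", "degree", "coefficient",
            "percentage", "masked")
  if (!all(need %in% names(df)))
    stop("file ", path, ": malformed report header")
  masked_rows <- df$masked %in% c("TRUE", TRUE)
  terms <- df[!masked_rows, c("metabolite", "term_label", "degree",
                              "coefficient", "percentage")]
  terms$degree <- as.integer(terms$degree)
  terms$coefficient <- as.numeric(terms$coefficient)
  terms$percentage <- as.numeric(terms$percentage)
  rownames(terms) <- NULL
  ids <- unique(df$metabolite)
  structure(list(terms = terms,
                 metabolite_ids = ids,
                 masked_metabolites = unique(df$metabolite[masked_rows]),
                 degenerate_metabolites = character(),
                 reference_levels = stats::setNames(
                   rep(NA_real_, length(ids)), ids)),
            class = "synergy_report")
}

#' Write the synergy matrix as CSV
#'
#' Rectangular metabolite x term matrix with empty cells for absent terms
#' and a final \code{masked} column flagging grey rows.
#'
#' @param report a \code{"synergy_report"}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
write_report_matrix <- function(report, path) {
  mat <- report_to_matrix(report)
  masked <- attr(mat, "masked")
  rows <- list(c("metabolite", colnames(mat), "masked"))
  for (i in seq_len(nrow(mat))) {
    vals <- ifelse(is.na(mat[i, ]), "", fmt_num(mat[i, ]))
    rows[[length(rows) + 1L]] <- c(rownames(mat)[i], vals,
                                   as.character(masked[i]))
  }
  write_table_lines(rows, path)
  invisible(path)
}

#' Read a Ct table from long-format CSV
#'
#' @param path CSV with columns \code{sample_id}, \code{target_id},
#'   \code{ct}.
#' @param normalizer_target,reference_sample see \code{\link{ct_table}}.
#' @return a \code{\link{ct_table}}.
#' @export
read_ct <- function(path, normalizer_target, reference_sample) {
  df <- read_table_checked(path)
  need <- c("sample_id", "target_id", "ct")
  if (!all(need %in% names(df)))
    stop("file ", path, ": malformed header, expected columns ",
         paste(need, collapse = ", "))
  df$ct <- check_numeric_column(df, "ct", path)
  ct_table(df, normalizer_target, reference_sample)
}

#' Write per-sample fold changes to CSV
#' @param fold_changes named numeric vector from
#'   \code{\link{delta_delta_ct}}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
write_fold_changes <- function(fold_changes, path) {
  rows <- c(list(c("sample_id", "fold_change")),
            lapply(seq_along(fold_changes), function(i)
              c(names(fold_changes)[i], fmt_num(fold_changes[i]))))
  write_table_lines(rows, path)
  invisible(path)
}

#' Serialize fitted MARS models to JSON
#'
#' Text serialization of a fitted panel so \code{fit} and \code{report} can
#' run as separate steps. Numbers are stored at full precision.
#'
#' @param models a \code{"mars_panel"} or list of \code{"mars"} models.
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
write_models <- function(models, path) {
  # reals are serialized as decimal strings (%.17g) so that fit -> report
  # in two steps is byte-identical to the one-shot report
  enc <- lapply(models, function(m) {
    list(response_id = m$response_id,
         n_obs = m$n_obs, n_vars = m$n_vars, var_names = m$var_names,
         rss = fmt_num(m$rss), gcv = fmt_num(m$gcv),
         coefficients = fmt_num(m$coefficients),
         gcv_penalty = fmt_num(m$config$gcv_penalty),
         bases = lapply(m$bases, function(b)
           list(vars = b$vars, knots = fmt_num(b$knots), dirs = b$dirs)))
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read fitted MARS models from JSON
#' @param path JSON written by \code{\link{write_models}}.
#' @return a \code{"mars_panel"} list of \code{"mars"} models.
#' @export
read_models <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  models <- lapply(enc, function(e) {
    bases <- lapply(e$bases, function(b)
      hinge_basis(vars = unlist(b$vars) %||% integer(),
                  knots = as.numeric(unlist(b$knots) %||% numeric()),
                  dirs = unlist(b$dirs) %||% integer()))
    structure(list(bases = bases,
                   coefficients = as.numeric(unlist(e$coefficients)),
                   rss = as.numeric(e$rss), gcv = as.numeric(e$gcv),
                   n_obs = e$n_obs,
                   n_vars = e$n_vars,
                   var_names = unlist(e$var_names),
                   response_id = e$response_id,
                   config = fit_config(
                     gcv_penalty = as.numeric(e$gcv_penalty)),
                   pruned = TRUE),
              class = "mars")
  })
  names(models) <- vapply(models, function(m) m$response_id %||% "",
                          character(1))
  structure(models, class = "mars_panel")
}
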