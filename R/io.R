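#' Read a time-series expression file
#'
#' Two TSV dialects are supported. `dream4`: a header line whose first field
#' is `Time` followed by gene names; data rows carry the time stamp in the
#' first column; blank lines separate independent time series (the header may
#' optionally be repeated after a blank line). `plain`: a headerless numeric
#' matrix, one gene per row, columns are time points, a single series; an
#' optional non-numeric first column is taken as gene names.
#'
#' @param path file path.
#' @param dialect `"dream4"` or `"plain"`.
#' @return a [as_expression()] table; for `dream4` the per-series time stamps
#'   are kept in a `time_labels` attribute.
#' @export
read_expression <- function(path, dialect = c("dream4", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (dialect == "plain") {
    return(parse_plain(lines, path))
  }
  parse_dream4(lines, path)
}

parse_dream4 <- function(lines, path) {
  is_blank <- !nzchar(trimws(lines))
  if (all(is_blank)) stop("empty expression file: ", path, call. = FALSE)
  first <- which(!is_blank)[1]
  header <- strsplit(lines[first], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || tolower(trimws(header[1])) != "time") {
    stop("dream4 header must start with 'Time': ", path, call. = FALSE)
  }
  genes <- trimws(header[-1])
  if (anyDuplicated(genes)) stop("duplicate gene name in header: ", path, call. = FALSE)

  blocks <- list()
  cur_rows <- list()
  cur_times <- numeric()
  flush <- function() {
    if (length(cur_rows)) {
      blocks[[length(blocks) + 1]] <<- list(
        mat = do.call(rbind, cur_rows), times = cur_times
      )
    }
    cur_rows <<- list()
    cur_times <<- numeric()
  }
  for (i in seq_along(lines)[-seq_len(first)]) {
    if (is_blank[i]) {
      flush()
      next
    }
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (identical(trimws(fields), trimws(header))) { # repeated header
      flush()
      next
    }
    if (length(fields) != length(header)) {
      stop(sprintf("line %d of %s: expected %d fields, found %d",
                   i, path, length(header), length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("line %d of %s: non-numeric value", i, path), call. = FALSE)
    }
    cur_times <- c(cur_times, vals[1])
    cur_rows[[length(cur_rows) + 1]] <- vals[-1]
  }
  flush()
  if (!length(blocks)) stop("no data rows in ", path, call. = FALSE)
  mats <- lapply(blocks, function(b) t(b$mat)) # genes x time
  out <- as_expression(mats, genes = genes)
  attr(out, "time_labels") <- lapply(blocks, `[[`, "times")
  out
}

parse_plain <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty expression file: ", path, call. = FALSE)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("line %d of %s: ragged row", bad, path), call. = FALSE)
  }
  first_num <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 1)))
  named <- anyNA(first_num)
  genes <- if (named) vapply(rows, `[[`, "", 1) else paste0("G", seq_along(rows))
  if (anyDuplicated(genes)) stop("duplicate gene name: ", path, call. = FALSE)
  num <- lapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(if (named) r[-1] else r))
    v
  })
  for (i in seq_along(num)) {
    if (anyNA(num[[i]])) stop(sprintf("line %d of %s: non-numeric value", i, path), call. = FALSE)
  }
  m <- do.call(rbind, num)
  rownames(m) <- genes
  as_expression(m)
}

#' Read a gold-standard edge list
#'
#' Headerless TSV with columns regulator, target, presence flag (1/0) and an
#' optional fourth sign column (`+`/`-` or `1`/`-1`). Rows with flag 0 are
#' kept only as explicit negatives and dropped from the edge set.
#'
#' @param path file path.
#' @return a tibble of class `pepn_gold` with columns `regulator`, `target`
#'   and (if present in the file) `sign` (+1/-1); attribute `signed`.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(!widths %in% c(3L, 4L))) {
    stop("gold standard rows must have 3 or 4 tab-separated fields", call. = FALSE)
  }
  if (length(unique(widths)) != 1) {
    stop("sign column present for some rows but not all", call. = FALSE)
  }
  reg <- vapply(rows, `[[`, "", 1)
  tar <- vapply(rows, `[[`, "", 2)
  flag <- as.integer(vapply(rows, `[[`, "", 3))
  if (anyNA(flag) || any(!flag %in% c(0L, 1L))) {
    stop("presence flag must be 0 or 1", call. = FALSE)
  }
  signed <- widths[1] == 4L
  keep <- flag == 1L
  out <- tibble::tibble(regulator = reg[keep], target = tar[keep])
  if (any(out$regulator == out$target)) stop("self edge in gold standard", call. = FALSE)
  if (signed) {
    s <- parse_sign(vapply(rows, `[[`, "", 4)[keep])
    out$sign <- s
  }
  if (anyDuplicated(out[c("regulator", "target")])) {
    stop("duplicate edge in gold standard", call. = FALSE)
  }
  as_gold(out, signed = signed)
}

parse_sign <- function(s) {
  s <- trimws(s)
  out <- ifelse(s %in% c("+", "1", "+1"), 1L, ifelse(s %in% c("-", "-1"), -1L, NA_integer_))
  if (anyNA(out)) stop("unrecognized sign value: ", s[is.na(out)][1], call. = FALSE)
  out
}

#' Construct a gold standard from a data frame
#'
#' @param edges data frame with columns `regulator`, `target`, optional `sign`.
#' @param signed whether edges carry regulation signs (defaults to presence of
#'   a `sign` column).
#' @return a `pepn_gold` tibble.
#' @export
as_gold <- function(edges, signed = "sign" %in% names(edges)) {
  out <- tibble::as_tibble(edges[c("regulator", "target", intersect("sign", names(edges)))])
  if (signed && !"sign" %in% names(out)) stop("signed gold needs a `sign` column", call. = FALSE)
  if (signed && anyNA(out$sign)) stop("signed gold has missing signs", call. = FALSE)
  if (any(out$regulator == out$target)) stop("self edge in gold standard", call. = FALSE)
  structure(out, signed = signed, class = c("pepn_gold", class(tibble::tibble())))
}

#' Read a transcription-factor list
#'
#' One gene identifier per line; blank lines ignored.
#'
#' @param path file path.
#' @return character vector of gene identifiers.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tfs <- trimws(readLines(path))
  tfs <- tfs[nzchar(tfs)]
  if (anyDuplicated(tfs)) stop("duplicate gene in TF list", call. = FALSE)
  tfs
}

#' Write / read ranked edge lists
#'
#' Ranked edges are written as TSV with header `regulator target sign score`,
#' sign rendered `+`/`-`, scores with 6 significant digits, sorted by
#' descending score with lexicographic (regulator, then target) tie-breaking.
#'
#' @param edges data frame with columns `regulator`, `target`, `sign`, `score`.
#' @param path output file path.
#' @return `write_ranked_edges()` returns `path` invisibly;
#'   `read_ranked_edges()` returns the edge tibble.
#' @export
write_ranked_edges <- function(edges, path) {
  edges <- rank_edges(edges)
  lines <- c(
    "regulator\ttarget\tsign\tscore",
    sprintf(
      "%s\t%s\t%s\t%s", edges$regulator, edges$target,
      ifelse(edges$sign > 0, "+", "-"), formatC(edges$score, digits = 6, format = "g")
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ranked_edges
#' @export
read_ranked_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = c(
    "character", "character", "character", "numeric"
  ))
  tibble::tibble(
    regulator = d$regulator, target = d$target,
    sign = parse_sign(d$sign), score = d$score
  )
}

#' Total ordering of a ranked edge list
#'
#' Sorts by descending score, breaking ties lexicographically by regulator
#' then target, so written edge files are totally ordered and reproducible.
#'
#' @param edges data frame with columns `regulator`, `target`, `score`.
#' @return the reordered tibble.
#' @export
rank_edges <- function(edges) {
  edges <- tibble::as_tibble(edges)
  edges[order(-edges$score, edges$regulator, edges$target, method = "radix"), ]
}

#' Export the inferred network as an extended Petri net structure
#'
#' Writes a Graphviz DOT file with one control place per regulator, one
#' output place per target, and per-target synthesis and decay transitions.
#' Activating regulators attach to the synthesis transition by read arcs
#' (rendered as dashed edges), inhibitors by write arcs (dotted, open arrow);
#' the decay transition is annotated with the gene's estimated decay
#' probability when a decay profile is supplied.
#'
#' @param edges signed edge data frame (`regulator`, `target`, `sign`, `score`).
#' @param path output `.dot` path.
#' @param decay optional [decay_probability()] result.
#' @return `path`, invisibly.
#' @export
export_pepn_structure <- function(edges, path, decay = NULL) {
  edges <- tibble::as_tibble(edges)
  genes <- sort(unique(c(edges$regulator, edges$target)))
  targets <- sort(unique(edges$target))
  dp <- function(g) {
    if (is.null(decay)) {
      return(NA_real_)
    }
    i <- match(g, decay$gene)
    if (is.na(i)) NA_real_ else decay$decay_prob[i]
  }
  q <- function(x) sprintf("\"%s\"", x)
  lines <- c(
    "digraph pepn {",
    "  rankdir=LR;",
    sprintf("  %s [shape=circle];", q(genes)) # places
  )
  for (t in targets) {
    syn <- sprintf("syn_%s", t)
    dec <- sprintf("dec_%s", t)
    dlab <- if (is.na(dp(t))) "decay" else sprintf("decay p=%.4g", dp(t))
    lines <- c(
      lines,
      sprintf("  %s [shape=box, style=filled, fillcolor=white, label=\"synthesis\"];", q(syn)),
      sprintf("  %s [shape=box, style=filled, fillcolor=grey, label=\"%s\"];", q(dec), dlab),
      sprintf("  %s -> %s;", q(syn), q(t)),
      sprintf("  %s -> %s;", q(t), q(dec))
    )
    sub <- edges[edges$target == t, ]
    for (i in seq_len(nrow(sub))) {
      style <- if (sub$sign[i] > 0) {
        "style=dashed, arrowhead=none, label=\"read\""
      } else {
        "style=dotted, arrowhead=odot, label=\"write\""
      }
      lines <- c(lines, sprintf(
        "  %s -> %s [%s];", q(sub$regulator[i]), q(syn), style
      ))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression()]. The `dream4` dialect writes a `Time`
#' header plus gene columns with blank lines between series; `plain` writes a
#' headerless genes-by-time matrix with gene names in the first column
#' (single series only).
#'
#' @param x a `pepn_expression` / `pepn_discretized` table.
#' @param path output path.
#' @param dialect `"dream4"` or `"plain"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, dialect = c("dream4", "plain")) {
  dialect <- match.arg(dialect)
  mats <- expression_matrices(x)
  genes <- gene_names(x)
  fmt <- function(v) formatC(v, digits = 6, format = "g")
  if (dialect == "plain") {
    if (length(mats) > 1) stop("plain dialect holds a single series", call. = FALSE)
    m <- mats[[1]]
    lines <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(genes[i], fmt(m[i, ])), collapse = "\t")
    }, "")
    writeLines(lines, path)
    return(invisible(path))
  }
  labels <- attr(x, "time_labels")
  lines <- paste(c("Time", genes), collapse = "\t")
  for (s in seq_along(mats)) {
    m <- mats[[s]]
    tl <- if (!is.null(labels)) labels[[s]] else seq_len(ncol(m)) - 1
    block <- vapply(seq_len(ncol(m)), function(j) {
      paste(c(fmt(tl[j]), fmt(m[, j])), collapse = "\t")
    }, "")
    lines <- c(lines, block, "")
  }
  writeLines(lines[-length(lines)], path)
  invisible(path)
}
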