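# Readers and writers: BoolNet-style ".bnet" model files, tabular BF
# collections (TSV) and the signed-network / fixed-point / hierarchy
# configuration trio.  Readers reject malformed input rather than
# coercing; writers emit a stable ordering.
#
# Integer output encodings: "integer-msb-row0" treats truth-table row 0
# as the most significant bit of the integer (so "0001" at k = 2 is 1);
# "integer-msb-rowlast" is the opposite endianness.  Decimal values are
# decoded through exact big-integer division so k > 5 tables survive.

#' Read a Boolean model from a .bnet file
#'
#' Expects the "targets, factors" convention: a header line, then one
#' \code{node, expression} line per node.  Regulator order is the order of
#' first appearance in the factor expression.  Constant factors \code{0} /
#' \code{1} become 0-input constants (accepted for dynamics, excluded from
#' classification).
#'
#' @param path file path.
#' @return a \code{\link{boolean_model}}.
#' @export
read_bnet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty .bnet file: ", path)
  header <- tolower(gsub("\\s", "", lines[1L]))
  if (header != "targets,factors")
    stop("missing 'targets, factors' header in ", path)
  body <- lines[-1L]
  split_at <- regexpr(",", body, fixed = TRUE)
  if (any(split_at < 0L))
    stop("line without 'target, factor' comma: ",
         body[which(split_at < 0L)[1L]])
  targets <- trimws(substr(body, 1L, split_at - 1L))
  exprs <- trimws(substr(body, split_at + 1L, nchar(body)))
  if (anyDuplicated(targets))
    stop("duplicate target line(s): ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "))
  if (any(exprs == "")) stop("empty factor expression for target ",
                             targets[which(exprs == "")[1L]])
  regulators <- list()
  functions <- list()
  for (i in seq_along(targets)) {
    ast <- .bf_parse(exprs[i])
    vars <- .bf_ast_vars(ast)
    undeclared <- setdiff(vars, targets)
    if (length(undeclared) > 0L)
      stop("factor of '", targets[i], "' references undeclared node(s): ",
           paste(undeclared, collapse = ", "))
    if (length(vars) == 0L) {
      env <- stats::setNames(list(0L), "..none")
      val <- .bf_ast_eval(ast, env)
      functions[[targets[i]]] <- boolfn(val[1L])
      regulators[[targets[i]]] <- character(0)
    } else {
      functions[[targets[i]]] <- bf_from_expression(exprs[i], vars)
      regulators[[targets[i]]] <- vars
    }
  }
  boolean_model(targets, regulators, functions)
}

# minimal disjunctive normal form of a truth table (for writing models
# whose functions did not come from an expression)
.bf_to_expression <- function(f, names) {
  k <- f$k
  if (k == 0L) return(as.character(f$outputs[1L]))
  lab <- classify_bf(f)
  if (lab$label != "NOT_NCF") return(ncf_expression(lab$form, names))
  ones <- which(f$outputs == 1L) - 1L
  if (length(ones) == 0L) return("0")
  if (length(ones) == 2^k) return("1")
  terms <- vapply(ones, function(r) {
    bits <- state_to_bits(r, k)
    paste(ifelse(bits == 1L, names, paste0("!", names)), collapse = " & ")
  }, character(1))
  paste0("(", paste(terms, collapse = ") | ("), ")")
}

#' Write a Boolean model to a .bnet file
#'
#' NCFs are written in nested-parenthesis normal form; other functions fall
#' back to a minterm expansion.  \code{read_bnet(write_bnet(m))} reproduces
#' the truth tables (and hence the state-transition graph) exactly.
#'
#' @param model a \code{\link{boolean_model}}.
#' @param path output path.
#' @export
write_bnet <- function(model, path) {
  lines <- "targets, factors"
  for (nd in model$nodes) {
    f <- model$functions[[nd]]
    regs <- model$regulators[[nd]]
    lines <- c(lines, paste0(nd, ", ", .bf_to_expression(f, regs)))
  }
  writeLines(lines, path)
  invisible(path)
}

.decode_output <- function(value, k, encoding) {
  n <- 2^k
  if (encoding == "bitstring") {
    if (!grepl("^[01]+$", value) || nchar(value) != n)
      stop("output '", substr(value, 1, 20), "' is not a ", n, "-bit string")
    return(as.integer(strsplit(value, "")[[1L]]))
  }
  if (!grepl("^[0-9]+$", value))
    stop("output '", value, "' is not a decimal integer")
  b <- big_from_string(value)
  bits <- integer(n)
  for (i in seq_len(n)) {
    qr <- big_div_small(b, 2, remainder = TRUE)
    bits[i] <- qr$r
    b <- qr$q
  }
  if (!big_is_zero(b))
    stop("integer output exceeds 2^", n, " - 1 for k = ", k)
  if (encoding == "integer-msb-row0") rev(bits)
  else if (encoding == "integer-msb-rowlast") bits
  else stop("unknown encoding: ", encoding)
}

.encode_output <- function(outputs, encoding) {
  if (encoding == "bitstring") return(paste(outputs, collapse = ""))
  bits <- if (encoding == "integer-msb-row0") outputs else rev(outputs)
  b <- big(0)
  for (bit in bits) {
    b <- big_mul_small(b, 2)
    if (bit == 1L) b <- big_add(b, big(1))
  }
  big_to_string(b)
}

#' Read a BF collection table
#'
#' Tab-separated columns \code{model_id}, \code{node}, \code{k},
#' \code{output}; a comment line \code{# encoding: <enc>} before the header
#' declares how \code{output} encodes the truth table (one of
#' \code{bitstring}, \code{integer-msb-row0}, \code{integer-msb-rowlast}).
#' Rows with more than \code{k_max} inputs are dropped with a message,
#' mirroring the usual restriction of reference datasets to at most 10
#' inputs.
#'
#' @param path file path.
#' @param k_max drop rows above this input count (default 10).
#' @return a \code{\link{bf_records}} data frame.
#' @export
read_bf_table <- function(path, k_max = 10L) {
  lines <- readLines(path, warn = FALSE)
  encoding <- "bitstring"
  enc_line <- grep("^#\\s*encoding\\s*:", lines)
  if (length(enc_line) > 0L)
    encoding <- trimws(sub("^#\\s*encoding\\s*:", "", lines[enc_line[1L]]))
  if (!encoding %in% c("bitstring", "integer-msb-row0", "integer-msb-rowlast"))
    stop("unknown encoding declaration: ", encoding)
  body <- lines[!startsWith(trimws(lines), "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           colClasses = "character")
  need <- c("model_id", "node", "k", "output")
  if (!all(need %in% names(tab)))
    stop("BF table must have columns: ", paste(need, collapse = ", "))
  k <- suppressWarnings(as.integer(tab$k))
  if (anyNA(k)) stop("non-integer k at row ", which(is.na(k))[1L])
  drop <- k > k_max
  if (any(drop))
    message("dropping ", sum(drop), " row(s) with k > ", k_max)
  tab <- tab[!drop, , drop = FALSE]
  k <- k[!drop]
  fns <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    fns[[r]] <- tryCatch(
      boolfn(.decode_output(tab$output[r], k[r], encoding), k[r]),
      error = function(e) stop("row ", r, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  bf_records(tab$model_id, tab$node, fns)
}

#' Write a BF collection table
#'
#' @param records a \code{\link{bf_records}} data frame.
#' @param path output path.
#' @param encoding output encoding (see \code{\link{read_bf_table}}).
#' @export
write_bf_table <- function(records, path, encoding = "bitstring") {
  stopifnot(encoding %in%
              c("bitstring", "integer-msb-row0", "integer-msb-rowlast"))
  enc <- vapply(records$fn, function(f)
    .encode_output(f$outputs, encoding), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# encoding: ", encoding), con)
  utils::write.table(
    data.frame(model_id = records$model_id, node = records$node,
               k = records$k, output = enc),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signed network + fixed points + selection configuration
#'
#' @param edges_path CSV with columns \code{source}, \code{target},
#'   \code{sign} (+1/-1).
#' @param fixedpoints_path CSV with a \code{name} column and one 0/1 column
#'   per node.
#' @param hierarchy text such as \code{"QC<VI,QC<CEI"}: comma-separated
#'   \code{less<more} pairs over declared cell-state names.
#' @return list with \code{network} (a \code{\link{signed_network}}),
#'   \code{fps} (matrix, named rows) and \code{hierarchy} (data frame).
#' @export
read_network_config <- function(edges_path, fixedpoints_path, hierarchy) {
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "sign") %in% names(edges)))
    stop("edges CSV needs columns source, target, sign")
  bad <- which(!edges$sign %in% c(-1, 1))
  if (length(bad) > 0L)
    stop("unknown sign token '", edges$sign[bad[1L]], "' on edge ",
         edges$source[bad[1L]], " -> ", edges$target[bad[1L]])
  fpt <- utils::read.csv(fixedpoints_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"name" %in% names(fpt)) stop("fixed-points CSV needs a 'name' column")
  fps <- as.matrix(fpt[, setdiff(names(fpt), "name"), drop = FALSE])
  rownames(fps) <- fpt$name
  if (!all(fps %in% c(0, 1))) stop("fixed-point states must be 0/1")
  network <- signed_network(edges, nodes = colnames(fps))
  hier <- NULL
  if (!is.null(hierarchy) && nzchar(hierarchy)) {
    parts <- trimws(strsplit(hierarchy, ",")[[1L]])
    mat <- regmatches(parts, regexec("^(.+?)\\s*<\\s*(.+)$", parts))
    if (any(lengths(mat) != 3L))
      stop("hierarchy entries must look like 'A<B'")
    hier <- data.frame(less = vapply(mat, `[`, "", 2L),
                       more = vapply(mat, `[`, "", 3L))
    undeclared <- setdiff(unique(c(hier$less, hier$more)), rownames(fps))
    if (length(undeclared) > 0L)
      stop("hierarchy names undeclared state(s): ",
           paste(undeclared, collapse = ", "))
  }
  list(network = network, fps = fps, hierarchy = hier)
}
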