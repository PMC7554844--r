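#' Read and write TI parameter sets
#'
#' JSON form: one flat object with keys `C1..C6`, `lambda_star`, `K` at
#' full double precision. CSV table form: one material per row with
#' columns exactly `name,C1,C2,C3,C4,C5,C6,lambda_star,K`. Both
#' round-trip losslessly.
#'
#' @param p a [ti_params()] object.
#' @param path file path.
#' @return `write_ti_params` returns `path` invisibly; `read_ti_params`
#'   a [ti_params()].
#' @export
write_ti_params <- function(p, path) {
  stopifnot(inherits(p, "ti_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ti_params
#' @export
read_ti_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("C1", "C2", "C3", "C4", "C5", "C6", "lambda_star", "K")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("read_ti_params: missing fields: ", paste(miss, collapse = ", "))
  ti_params(C1 = x$C1, C2 = x$C2, C3 = x$C3, C4 = x$C4, C5 = x$C5,
            C6 = x$C6, lambda_star = x$lambda_star, K = x$K)
}

#' @rdname write_ti_params
#' @param tbl named list of [ti_params()] (names become the `name`
#'   column).
#' @export
write_ti_table <- function(tbl, path) {
  rows <- do.call(rbind, lapply(names(tbl), function(nm) {
    p <- tbl[[nm]]
    data.frame(name = nm, C1 = p$C1, C2 = p$C2, C3 = p$C3, C4 = p$C4,
               C5 = p$C5, C6 = p$C6, lambda_star = p$lambda_star, K = p$K)
  }))
  utils::write.csv(format(rows, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ti_params
#' @export
read_ti_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "C1", "C2", "C3", "C4", "C5", "C6", "lambda_star", "K")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_ti_table: missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    ti_params(C1 = df$C1[i], C2 = df$C2[i], C3 = df$C3[i], C4 = df$C4[i],
              C5 = df$C5[i], C6 = df$C6[i], lambda_star = df$lambda_star[i],
              K = df$K[i]))
  names(out) <- df$name
  out
}

#' Read and write graded stacks as CSV
#'
#' Columns `t,X2,phi,psi,C1,C2,C3,C4,C5,C6,lambda_star,K,f`, one row per
#' layer, full double precision.
#'
#' @param stack a `"graded_stack"`; @param path file path.
#' @export
write_stack_csv <- function(stack, path) {
  df <- as.data.frame(stack)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "X2", "phi", "psi", "C1", "C2", "C3", "C4", "C5", "C6",
            "lambda_star", "K", "f")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_stack_csv: missing columns: ", paste(miss, collapse = ", "))
  layers <- lapply(seq_len(nrow(df)), function(i)
    ti_params(C1 = df$C1[i], C2 = df$C2[i], C3 = df$C3[i], C4 = df$C4[i],
              C5 = df$C5[i], C6 = df$C6[i], lambda_star = df$lambda_star[i],
              K = df$K[i]))
  structure(list(T = nrow(df), coords = df$X2, phi = df$phi, psi = df$psi,
                 layers = layers, f = df$f),
            class = "graded_stack")
}

#' Serialize a distribution specification as JSON
#'
#' @param spec a [dist_spec()]; @param path file path.
#' @export
write_dist_spec <- function(spec, path) {
  stopifnot(inherits(spec, "dist_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dist_spec
#' @export
read_dist_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dist_spec(x$family, unlist(x$p), lapply(x$domain, unlist))
}

#' Parse a "family:p1,p2,..." distribution string
#'
#' Command-line shorthand, e.g. `"symmetric_sigmoid:2,2"` or
#' `"asymmetric_sigmoid:0.301,1.084"`.
#'
#' @param s the string; @param domain coordinate domain for the spec.
#' @return a [dist_spec()].
#' @export
parse_dist_string <- function(s, domain = list(X2 = c(0, 1))) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  fam <- parts[1]
  p <- if (length(parts) > 1 && nzchar(parts[2]))
    suppressWarnings(as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]]))
  else numeric()
  if (any(is.na(p))) stop("parse_dist_string: non-numeric parameter in '", s, "'")
  dist_spec(fam, p, domain)
}
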