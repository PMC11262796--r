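# Native tabular model format: two UTF-8 tab-separated tables.
#   reactions.tsv:   id  equation  lb  ub  gpr  subsystem
#   metabolites.tsv: id  compartment  name
# Equation strings look like "glc_c + 2 adp_c -> 2 pyr_c + 2 atp_c";
# "<=>" is a cosmetic synonym for "->" (bounds are authoritative for
# reversibility). One side may be empty for boundary reactions.

format_equation <- function(model, reaction_id) {
  st <- model$stoichiometry[model$stoichiometry$reaction == reaction_id, , drop = FALSE]
  side <- function(rows) {
    if (nrow(rows) == 0) return("")
    co <- abs(rows$coef)
    paste(ifelse(co == 1, rows$metabolite, paste(format(co, trim = TRUE), rows$metabolite)),
          collapse = " + ")
  }
  i <- match(reaction_id, model$reactions$id)
  arrow <- if (model$reactions$lb[i] < 0) "<=>" else "->"
  paste(side(st[st$coef < 0, ]), arrow, side(st[st$coef > 0, ]))
}

parse_equation <- function(eq, reaction_id, line = NA) {
  where <- if (is.na(line)) reaction_id else sprintf("%s (line %d)", reaction_id, line)
  m <- regexpr("->|<=>|<->|=>", eq)
  if (m == -1) stop("equation for ", where, " has no arrow ('->' or '<=>'): '", eq, "'")
  arrow <- regmatches(eq, m)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2) stop("equation for ", where, " has multiple arrows: '", eq, "'")
  lhs <- if (length(sides) >= 1) sides[1] else ""
  rhs <- if (length(sides) == 2) sides[2] else ""
  parse_side <- function(side, sgn) {
    side <- trimws(side)
    if (!nzchar(side)) return(NULL)
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- lapply(terms, function(tm) {
      if (!nzchar(tm)) stop("empty term in equation for ", where, ": '", eq, "'")
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1) {
        data.frame(metabolite = parts, coef = sgn, stringsAsFactors = FALSE)
      } else if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[1])))) {
        data.frame(metabolite = parts[2], coef = sgn * as.numeric(parts[1]),
                   stringsAsFactors = FALSE)
      } else {
        stop("cannot parse term '", tm, "' in equation for ", where)
      }
    })
    do.call(rbind, out)
  }
  st <- rbind(parse_side(lhs, -1), parse_side(rhs, +1))
  if (is.null(st) || nrow(st) == 0) stop("equation for ", where, " is empty")
  st$reaction <- reaction_id
  st[, c("reaction", "metabolite", "coef")]
}

#' Write a model in the native tabular format
#'
#' Emits `reactions.tsv` and `metabolites.tsv` into `dir`. The pair
#' round-trips exactly through [read_native_model()] (ids, stoichiometry,
#' bounds, GPR strings).
#'
#' @param model a `metabolic_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_native_model <- function(model, dir) {
  validate_model(model)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rx <- model$reactions
  rx$equation <- vapply(rx$id, function(id) format_equation(model, id), character(1))
  rx <- rx[, c("id", "equation", "lb", "ub", "gpr", "subsystem")]
  write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  write.table(model$metabolites, file.path(dir, "metabolites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' Read a model from the native tabular format
#'
#' @param dir directory containing `reactions.tsv` and `metabolites.tsv` as
#'   written by [write_native_model()].
#' @param id model identifier for the returned object.
#' @return A validated `metabolic_model`.
#' @export
read_native_model <- function(dir, id = basename(dir)) {
  rx_path <- file.path(dir, "reactions.tsv")
  met_path <- file.path(dir, "metabolites.tsv")
  for (p in c(rx_path, met_path)) if (!file.exists(p)) stop("missing file: ", p)
  rx <- read.delim(rx_path, stringsAsFactors = FALSE, na.strings = NULL,
                   colClasses = "character")
  met <- read.delim(met_path, stringsAsFactors = FALSE, na.strings = NULL,
                    colClasses = "character")
  need <- c("id", "equation", "lb", "ub", "gpr", "subsystem")
  missing_cols <- setdiff(need, names(rx))
  if (length(missing_cols)) {
    stop("reactions.tsv is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(c("id", "compartment") %in% names(met))) {
    stop("metabolites.tsv needs columns id and compartment")
  }
  if (is.null(met$name)) met$name <- met$id
  lb <- suppressWarnings(as.numeric(rx$lb)); ub <- suppressWarnings(as.numeric(rx$ub))
  bad <- which(is.na(lb) | is.na(ub))
  if (length(bad)) {
    stop(sprintf("non-numeric bounds in reactions.tsv line %d (reaction %s)",
                 bad[1] + 1L, rx$id[bad[1]]))
  }
  st <- do.call(rbind, lapply(seq_len(nrow(rx)), function(i) {
    parse_equation(rx$equation[i], rx$id[i], line = i + 1L)
  }))
  reactions <- data.frame(id = rx$id, lb = lb, ub = ub, gpr = rx$gpr,
                          subsystem = rx$subsystem, stringsAsFactors = FALSE)
  metabolic_model(met, reactions, st, id = id,
                  provenance = paste("read from native format:", dir))
}
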