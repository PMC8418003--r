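# Shared helpers: symbol normalization and classed errors.

#' Normalize gene symbols
#'
#' The single casing rule used by every reader and generator: trim
#' whitespace and uppercase. Identifier reconciliation across inputs is by
#' exact normalized-symbol match only; no alias resolution is attempted.
#'
#' @param x character vector of gene symbols.
#' @return character vector, trimmed and uppercased.
#' @export
normalizeSymbols <- function(x) {
    toupper(trimws(as.character(x)))
}

# stop() with a condition class so callers/tests can discriminate causes
npStop <- function(class, fmt, ...) {
    msg <- sprintf(fmt, ...)
    stop(structure(
        class = c(class, "netprop_error", "error", "condition"),
        list(message = msg, call = sys.call(-1))))
}

# read a delimited text table, sniffing tab vs comma from the extension
readDelimited <- function(path, header = FALSE) {
    if (!file.exists(path))
        npStop("netprop_input_error", "cannot read file '%s'", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tryCatch(
        utils::read.table(path, header = header, sep = sep, quote = "",
            comment.char = "#", stringsAsFactors = FALSE,
            check.names = FALSE, blank.lines.skip = TRUE),
        error = function(e) {
            if (grepl("no lines available", conditionMessage(e)))
                npStop("netprop_empty_input_error",
                    "file '%s' contains no records", path)
            npStop("netprop_input_error", "cannot parse '%s': %s",
                path, conditionMessage(e))
        })
}
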