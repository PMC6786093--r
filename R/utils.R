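# Internal helpers: condition classes, name normalisation, deterministic order.

# Condition classes map onto the CLI exit-code contract:
#   mc_usage_error -> 2, mc_format_error -> 3, mc_numeric_error -> 4.
stop_usage <- function(msg, ...) {
  stop(structure(class = c("mc_usage_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_format <- function(msg, ...) {
  stop(structure(class = c("mc_format_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_numeric <- function(msg, ...) {
  stop(structure(class = c("mc_numeric_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Disease names are MeSH-styled but case and spacing drift between sources;
# matching is exact case-insensitive after whitespace/comma normalisation.
normalize_disease_name <- function(x) {
  x <- trimws(x)
  x <- gsub("\\s*,\\s*", ", ", x)
  x <- gsub("\\s+", " ", x)
  tolower(x)
}

# Locale-independent lexicographic order so entity indices are reproducible
# across platforms.
lex_sort <- function(x) sort(unique(x), method = "radix")

lex_order <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x <= 1
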