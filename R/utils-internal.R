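# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical CYP id: family digits + subfamily letter + optional member digits
# (covers 2D6, 2C19, 3A43, 11B1, 4F12, 2W1, 19A1, ...)
.cyp_id_regex <- "^[0-9]{1,2}[A-Za-z][0-9]{0,2}$"

is_cyp_id <- function(x) grepl(.cyp_id_regex, x)

canonical_cyp <- function(x) toupper(trimws(x))

stop_cypscope <- function(...) stop(..., call. = FALSE)

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_rng_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) stop_cypscope("file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", quote = "",
                         comment.char = "", na.strings = NULL)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop_cypscope("missing required column(s) in ", path, ": ",
                  paste(missing, collapse = ", "))
  x
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
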