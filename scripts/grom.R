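#!/usr/bin/env Rscript
# Thin launcher for the staged GROM pipeline; all logic lives in the
# installed package.  See `Rscript scripts/grom.R --help`.
suppressPackageStartupMessages(library(grom))
status <- grom_cli(commandArgs(trailingOnly = TRUE))
quit(status = if (is.numeric(status)) status else 0L, save = "no")
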