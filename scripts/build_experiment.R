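#!/usr/bin/env Rscript
# Build one participant's full experiment: schedule manifest (JSON-lines)
# plus rendered MIDI stimuli.
#
# Usage:
#   Rscript scripts/build_experiment.R --seed <int> --tonic-condition <0-5> \
#       --out <directory>

suppressPackageStartupMessages(library(icmelody))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) return(default)
  args[i + 1L]
}
seed <- as.integer(get_arg("--seed", "1"))
tonic <- as.integer(get_arg("--tonic-condition", "0"))
out_dir <- get_arg("--out", "experiment_out")

spec <- default_grammar()
stopifnot(nrow(validate_grammar(spec)) == 0)

schedule <- build_experiment(spec, tonic_index = tonic, seed = seed)
mapping <- build_pitch_mapping(hexascale(), tonic)

dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
write_schedule_manifest(schedule, file.path(out_dir, "schedule.jsonl"))
files <- render_schedule_midi(schedule, mapping,
                              file.path(out_dir, "stimuli"))
utils::write.csv(generics::tidy(mapping),
                 file.path(out_dir, "pitch_mapping.csv"),
                 row.names = FALSE)

cat(sprintf("wrote %d trials, %d MIDI stimuli to %s (tonic condition %d)\n",
            nrow(schedule$trials), nrow(files), out_dir, tonic))
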