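# same premise, different constant meal levels: saved for expert opinion
S22: Food(f), has-glycemic-index(f,gi), lessThanOrEqual(gi,70) -> has-meal-level(f,high-level)
S22C: Food(f), has-glycemic-index(f,gi), lessThanOrEqual(gi,70) -> has-meal-level(f,very-low-level)
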