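File type = "ooTextFile"
Object class = "TextGrid"

xmin = 0
xmax = 2
tiers? <exists>
size = 2
item []:
    item [1]:
        class = "TextTier"
        name = "stress_onsets"
        xmin = 0
        xmax = 2
        points: size = 4
        points [1]:
            number = 0.125
            mark = "MA"
        points [2]:
            number = 0.625
            mark = "MA"
        points [3]:
            number = 1.125
            mark = "QUITE"
        points [4]:
            number = 1.625
            mark = "TRA"
    item [2]:
        class = "IntervalTier"
        name = "syllables"
        xmin = 0
        xmax = 2
        intervals: size = 5
        intervals [1]:
            xmin = 0
            xmax = 0.25
            text = "ma"
        intervals [2]:
            xmin = 0.25
            xmax = 0.5
            text = "ry"
        intervals [3]:
            xmin = 0.5
            xmax = 0.75
            text = ""
        intervals [4]:
            xmin = 0.75
            xmax = 1.0
            text = "ma"
        intervals [5]:
            xmin = 1.0
            xmax = 1.25
            text = "ry"
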