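File type = "ooTextFile"
Object class = "TextGrid"

xmin = 0.000000
xmax = 0.486443
tiers? <exists>
size = 1
item []:
    item [1]:
        class = "IntervalTier"
        name = "elements"
        xmin = 0.000000
        xmax = 0.486443
        intervals: size = 17
        intervals [1]:
            xmin = 0.000000
            xmax = 0.025449
            text = "A"
        intervals [2]:
            xmin = 0.025449
            xmax = 0.042415
            text = ""
        intervals [3]:
            xmin = 0.042415
            xmax = 0.064756
            text = "B"
        intervals [4]:
            xmin = 0.064756
            xmax = 0.079649
            text = ""
        intervals [5]:
            xmin = 0.079649
            xmax = 0.127465
            text = "C"
        intervals [6]:
            xmin = 0.127465
            xmax = 0.159343
            text = ""
        intervals [7]:
            xmin = 0.159343
            xmax = 0.244039
            text = "D"
        intervals [8]:
            xmin = 0.244039
            xmax = 0.300503
            text = ""
        intervals [9]:
            xmin = 0.300503
            xmax = 0.323816
            text = "E"
        intervals [10]:
            xmin = 0.323816
            xmax = 0.339358
            text = ""
        intervals [11]:
            xmin = 0.339358
            xmax = 0.369241
            text = "F"
        intervals [12]:
            xmin = 0.369241
            xmax = 0.389163
            text = ""
        intervals [13]:
            xmin = 0.389163
            xmax = 0.408041
            text = "G"
        intervals [14]:
            xmin = 0.408041
            xmax = 0.420626
            text = ""
        intervals [15]:
            xmin = 0.420626
            xmax = 0.439753
            text = "H"
        intervals [16]:
            xmin = 0.439753
            xmax = 0.452505
            text = ""
        intervals [17]:
            xmin = 0.452505
            xmax = 0.486443
            text = "I"
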