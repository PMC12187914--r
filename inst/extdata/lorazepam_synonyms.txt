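# Lorazepam screening keywords: generic name plus trade names
lorazepam
ATIVAN
LORAZ
LOREEV XR
Témesta
Donix
Duralozam
Laubeel
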