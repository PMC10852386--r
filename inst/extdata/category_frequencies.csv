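category,count
cut_pierce,444
drowning,144
fall,8422
fire_burn,2034
multiple,316
environmental,1384
transport,3835
poisoning,2499
struck_by_against,1449
suffocation,663
other_specified,1513
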