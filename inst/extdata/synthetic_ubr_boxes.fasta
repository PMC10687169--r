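>UBR1 synthetic UBR-box-like sequence
WLMGCDRKQCAICKTPDGMGSCNSQSPSWHMWAHIEWWECYEFCSVIEESPYKDCFRCINYHVIQNMALR
>UBR2 synthetic UBR-box-like sequence
TLRGCERKQCIICKVPNMMDSCLSQSPNSHMWWHIEWWMCDEFCRVERPGPYKKCFRCINRHVIQEDALR
>UBR3 synthetic UBR-box-like sequence
EWIGCVEVQCIICYQPDSWMMFSCNSQSPNSHGSAHIIWWMCYEFCVVEQELPYKDCFRCIMMHVIQEIALR
>UBR4 synthetic UBR-box-like sequence
ELEGCVRKQCIICKVPDMMLSCNSQSKNSHMWAHIEWWMCYEFCSVEYEGWYEDCVRCINNCVIQELALR
>UBR5 synthetic UBR-box-like sequence
ELEGCVRIQCIICKNPDMMGSCNLQSPNEHMWAHFEWWSCGAFCSVEKPYKDCFMCANYCVVQKIQVR
>UBR6 synthetic UBR-box-like sequence
ELEGCVFTQCIICKVPPSYMMESCNSLQPNSHPSAHIYVWMCYLFCSVEAEGDYKDCFNCINKCVIEEIAPR
>UBR7 synthetic UBR-box-like sequence
ELRKCVRKECITCMVPDMQGSCNKQSVNKHPWAHIEWWVCYEFCTVEGPYADCMRCINYCVVEEIALR
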