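>TcpP_synthetic synthetic single-TM anchor (not the natural sequence); TM 161-181
QPSTPEKTEPTNYSENHDGSTKTGSNTTQGSPDSDDKKTPRTDEKKGREDQTTDSHNESK
KGRKSKNSHEGQYSPNKQGKKRNEPTRSRSRTESNRKRSSHREKTKEGKSGTSSRTTSSK
HRQTKHREDTTNTKNKDGPERNDRRPGPTERESKQTPHPRGVLILAIFVGLSMFLVSLLI
GQRDGTSRRQSNSGSPEESGSQPNNTERPDQKKEEQDRDNN
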